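#' Define a protein-DNA contact distance
#'
#' A contact is the distance between the charged side-chain anchor of a
#' lysine (N-zeta) or arginine (C-zeta) and a backbone phosphate P atom of
#' the primer or template DNA strand. The anchor atom is fixed by the
#' residue type; supplying a conflicting \code{anchor_atom} is an error.
#'
#' @param residue_name "LYS" or "ARG".
#' @param residue_number,chain protein residue number and chain id.
#' @param strand "primer" or "template" (metadata; the atoms are located via
#'   \code{dna_chain}/\code{dna_resno}).
#' @param base_pair base-pair index (metadata, used for de-duplication).
#' @param dna_resno,dna_chain residue number and chain of the nucleotide
#'   whose P atom is measured.
#' @param anchor_atom optional; must match the residue type
#'   ("NZ" for LYS, "CZ" for ARG).
#' @param descriptor_id optional identifier (default constructed from the
#'   residue and base pair).
#' @return one-row data.frame usable in \code{\link{compute_contact_distances}}.
#' @export
contact_definition <- function(residue_name, residue_number, chain,
                               strand = c("primer", "template"),
                               base_pair, dna_resno, dna_chain,
                               anchor_atom = NULL, descriptor_id = NULL) {
  strand <- match.arg(strand)
  residue_name <- toupper(residue_name)
  expected <- switch(residue_name, LYS = "NZ", ARG = "CZ",
                     stop("contact definitions support LYS (NZ) and ARG (CZ), got ",
                          residue_name, call. = FALSE))
  if (!is.null(anchor_atom) && toupper(anchor_atom) != expected)
    stop("anchor atom ", anchor_atom, " is inconsistent with residue type ",
         residue_name, " (expected ", expected, ")", call. = FALSE)
  if (is.null(descriptor_id))
    descriptor_id <- paste0(residue_name, residue_number, "-",
                            ifelse(strand == "primer", "P", "T"), base_pair)
  data.frame(descriptor_id = descriptor_id, residue_name = residue_name,
             residue_number = residue_number, chain = chain,
             anchor_atom = expected, strand = strand, base_pair = base_pair,
             dna_resno = dna_resno, dna_chain = dna_chain,
             residue_label = paste0(residue_name, residue_number),
             base_pair_label = paste0(ifelse(strand == "primer", "P", "T"),
                                      base_pair),
             stringsAsFactors = FALSE)
}

#' Compute contact distances from a structure or multi-model trajectory
#'
#' Reads a PDB file (single- or multi-model) with \pkg{bio3d} and computes
#' the Euclidean anchor-to-phosphate distance (in Angstrom) for each contact
#' definition, one column per contact, frame order preserved.
#'
#' @param structure a path to a PDB file or a \code{bio3d} \code{pdb} object.
#' @param definitions data.frame of stacked \code{\link{contact_definition}}
#'   rows.
#' @return a \code{\link{descriptor_table}}.
#' @export
compute_contact_distances <- function(structure, definitions) {
  if (is.character(structure))
    structure <- bio3d::read.pdb(structure, multi = TRUE)
  if (!inherits(structure, "pdb"))
    stop("structure must be a PDB path or bio3d pdb object", call. = FALSE)
  atoms <- structure$atom
  xyz <- structure$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  locate <- function(resno, chain, elety, what) {
    idx <- which(atoms$resno == resno & atoms$chain == chain &
                 trimws(atoms$elety) == elety)
    if (length(idx) == 0L)
      stop("resolution error: atom ", elety, " of ", what,
           " (resno ", resno, ", chain ", chain, ") not found", call. = FALSE)
    if (length(idx) > 1L)
      stop("definition error: atom ", elety, " of ", what,
           " is ambiguous in chain ", chain, call. = FALSE)
    idx
  }
  n_frames <- nrow(xyz)
  vals <- matrix(0, n_frames, nrow(definitions),
                 dimnames = list(NULL, definitions$descriptor_id))
  for (j in seq_len(nrow(definitions))) {
    d <- definitions[j, ]
    in_res <- which(atoms$resno == d$residue_number & atoms$chain == d$chain)
    if (length(in_res) == 0L)
      stop("resolution error: no residue with resno ", d$residue_number,
           " in chain ", d$chain, call. = FALSE)
    res_name <- trimws(atoms$resid[in_res[1L]])
    if (res_name != d$residue_name)
      stop("definition error: residue ", d$residue_number, " chain ", d$chain,
           " is ", res_name, ", not ", d$residue_name, call. = FALSE)
    ia <- locate(d$residue_number, d$chain, d$anchor_atom, d$residue_label)
    ip <- locate(d$dna_resno, d$dna_chain, "P",
                 paste0("nucleotide ", d$dna_resno))
    ca <- xyz[, (3 * ia - 2):(3 * ia), drop = FALSE]
    cp <- xyz[, (3 * ip - 2):(3 * ip), drop = FALSE]
    vals[, j] <- sqrt(rowSums((ca - cp)^2))
  }
  descriptor_table(vals, definitions)
}

#' Three-rule contact filter
#'
#' Screens a candidate descriptor pool against two state ensembles with the
#' rules, applied in order:
#' \enumerate{
#'   \item \emph{presence}: the distance is within \code{presence_cutoff} in
#'     at least \code{presence_fraction} of the frames of at least one state;
#'   \item \emph{separation}: the state means differ by more than two
#'     standard deviations, \eqn{|m_A - m_B| > 2\,\max(s_A, s_B)} (or the
#'     pooled-SD variant);
#'   \item \emph{de-duplication}: one survivor per residue-base-pair group,
#'     keeping the largest rule-(ii) margin (ties broken by descriptor id).
#' }
#' Every rejected descriptor records the first rule that failed.
#'
#' @param table_a,table_b \code{descriptor_table}s for the two states with
#'   identical descriptor inventories.
#' @param presence_cutoff distance (Angstrom) below which a contact counts
#'   as present; default 6.0.
#' @param presence_fraction minimum fraction of present frames (default 0.5).
#' @param sd_rule "max" (conservative two-sided default) or "pooled".
#' @return list with \code{retained} (character ids, input order) and
#'   \code{report} (per-descriptor decision data.frame).
#' @export
filter_descriptors <- function(table_a, table_b, presence_cutoff = 6.0,
                               presence_fraction = 0.5,
                               sd_rule = c("max", "pooled")) {
  sd_rule <- match.arg(sd_rule)
  stopifnot(inherits(table_a, "descriptor_table"),
            inherits(table_b, "descriptor_table"))
  A <- table_a$values
  B <- table_b$values
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("input error: empty descriptor table", call. = FALSE)
  if (!identical(colnames(A), colnames(B)))
    stop("schema error: descriptor inventories differ between states",
         call. = FALSE)
  meta <- table_a$meta
  ids <- colnames(A)
  group <- if (all(c("residue_label", "base_pair_label") %in% names(meta))) {
    paste(meta$residue_label, meta$base_pair_label, sep = "|")
  } else ids
  pres_a <- colMeans(A <= presence_cutoff)
  pres_b <- colMeans(B <= presence_cutoff)
  m_a <- colMeans(A)
  m_b <- colMeans(B)
  s_a <- apply(A, 2, sd)
  s_b <- apply(B, 2, sd)
  s_ref <- if (sd_rule == "max") pmax(s_a, s_b) else
    sqrt(((nrow(A) - 1) * s_a^2 + (nrow(B) - 1) * s_b^2) /
           (nrow(A) + nrow(B) - 2))
  margin <- abs(m_a - m_b) - 2 * s_ref
  rule <- rep("none", length(ids))
  pass1 <- pres_a >= presence_fraction | pres_b >= presence_fraction
  rule[!pass1] <- "presence"
  pass2 <- pass1 & margin > 0
  rule[pass1 & !pass2] <- "separation"
  retained <- pass2
  for (g in unique(group[pass2])) {
    in_g <- which(pass2 & group == g)
    if (length(in_g) > 1L) {
      ord <- in_g[order(-margin[in_g], ids[in_g])]
      drop <- ord[-1L]
      retained[drop] <- FALSE
      rule[drop] <- "dedup"
    }
  }
  report <- data.frame(
    descriptor_id = ids, retained = retained, removing_rule = rule,
    presence_a = pres_a, presence_b = pres_b,
    mean_a = m_a, mean_b = m_b, sd_a = s_a, sd_b = s_b,
    margin = margin, group = group, row.names = NULL,
    stringsAsFactors = FALSE)
  list(retained = ids[retained], report = report)
}

# subset a descriptor table to the given descriptor ids (keeping order)
#' Subset a descriptor table by descriptor id
#' @param table a \code{descriptor_table}.
#' @param ids character vector of descriptor ids to keep.
#' @export
subset_descriptors <- function(table, ids) {
  stopifnot(inherits(table, "descriptor_table"))
  j <- match(ids, colnames(table$values))
  if (anyNA(j)) stop("schema error: unknown descriptor id(s): ",
                     paste(ids[is.na(j)], collapse = ", "), call. = FALSE)
  descriptor_table(table$values[, j, drop = FALSE],
                   table$meta[j, , drop = FALSE], table$labels)
}
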