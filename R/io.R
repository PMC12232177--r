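#' Write a COLVAR-style whitespace table
#'
#' Writes the biased-sampling community's plain-text time-series format:
#' a \code{#! FIELDS ...} header line followed by whitespace-separated
#' rows, at full double precision.
#'
#' @param table data.frame of numeric columns.
#' @param path output file.
#' @export
write_colvar <- function(table, path) {
  stopifnot(is.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(table), collapse = " ")), con)
  body <- do.call(paste, c(lapply(table, function(v) sprintf("%.17g", v)),
                           sep = " "))
  writeLines(body, con)
  invisible(path)
}

#' Read a COLVAR-style whitespace table
#'
#' @param path input file.
#' @return data.frame with the columns named in the FIELDS header.
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#! FIELDS"))
    stop("parse error at line 1: missing '#! FIELDS' header", call. = FALSE)
  fields <- strsplit(sub("^#! FIELDS\\s+", "", lines[1L]), "\\s+")[[1L]]
  body <- lines[-1L]
  body <- body[!startsWith(body, "#") & nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(rows) != length(fields))
  if (length(bad))
    stop("parse error at line ", bad[1L] + 1L, ": expected ",
         length(fields), " columns, found ", lengths(rows)[bad[1L]],
         call. = FALSE)
  out <- as.data.frame(lapply(seq_along(fields), function(k)
    as.numeric(vapply(rows, `[`, character(1), k))))
  names(out) <- fields
  out
}

#' Export a trajectory as a COLVAR-style table
#'
#' Fields: time, cv1 (cv2), opes.bias, weight, plus the latent coordinates
#' x1, x2 when present.
#'
#' @param trajectory a \code{trajectory}.
#' @param path output file.
#' @export
write_trajectory_colvar <- function(trajectory, path) {
  df <- data.frame(time = trajectory$time)
  if (!is.null(trajectory$cv)) {
    cvn <- paste0("cv", seq_len(ncol(trajectory$cv)))
    for (k in seq_along(cvn)) df[[cvn[k]]] <- trajectory$cv[, k]
    df[["opes.bias"]] <- trajectory$bias
  }
  if (!is.null(trajectory$weights)) df$weight <- trajectory$weights
  df$x1 <- trajectory$latent[, 1]
  df$x2 <- trajectory$latent[, 2]
  write_colvar(df, path)
}

#' Write / read a descriptor table as CSV with a metadata header block
#'
#' The per-descriptor metadata travels as commented \code{# meta} lines
#' above the CSV body, so a single file round-trips the whole object.
#'
#' @param table a \code{descriptor_table}.
#' @param path file path.
#' @export
write_descriptor_table <- function(table, path) {
  stopifnot(inherits(table, "descriptor_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# opescv descriptor_table v1", con)
  meta <- table$meta
  writeLines(paste0("# metafields ", paste(names(meta), collapse = ",")), con)
  for (i in seq_len(nrow(meta)))
    writeLines(paste0("# meta ",
                      paste(vapply(meta[i, ], as.character, character(1)),
                            collapse = ",")), con)
  has_lab <- !is.null(table$labels)
  header <- c(if (has_lab) "state", colnames(table$values))
  writeLines(paste(header, collapse = ","), con)
  vals <- apply(table$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  if (has_lab) vals <- paste(table$labels, vals, sep = ",")
  writeLines(vals, con)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "# meta ")]
  mf_line <- lines[startsWith(lines, "# metafields ")]
  if (length(mf_line) != 1L)
    stop("parse error: missing metadata header block", call. = FALSE)
  fields <- strsplit(sub("^# metafields ", "", mf_line), ",")[[1L]]
  meta <- do.call(rbind, lapply(meta_lines, function(l)
    strsplit(sub("^# meta ", "", l), ",")[[1L]]))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  names(meta) <- fields
  for (k in names(meta)) {
    conv <- suppressWarnings(as.numeric(meta[[k]]))
    if (!anyNA(conv)) meta[[k]] <- conv
  }
  body <- lines[!startsWith(lines, "#")]
  con <- textConnection(body)
  on.exit(close(con))
  df <- read.csv(con, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- NULL
  if (names(df)[1L] == "state") {
    labels <- df$state
    df$state <- NULL
  }
  descriptor_table(as.matrix(df), meta, labels)
}

# ---------------------------------------------------------------------------
# Model serialization: portable JSON with explicit matrix shapes
# ---------------------------------------------------------------------------

pack_obj <- function(x) {
  if (is.matrix(x)) {
    list(`_type` = "matrix", dim = dim(x),
         dimnames = dimnames(x), data = as.numeric(x))
  } else if (is.list(x)) {
    out <- lapply(x, pack_obj)
    attr(out, "names") <- names(x)
    out
  } else x
}

unpack_obj <- function(x) {
  if (is.list(x) && identical(x[["_type"]], "matrix")) {
    m <- matrix(unlist(x$data), x$dim[[1]], x$dim[[2]])
    if (!is.null(x$dimnames))
      dimnames(m) <- lapply(x$dimnames, function(d)
        if (is.null(d) || length(d) == 0) NULL else unlist(d))
    m
  } else if (is.list(x)) {
    lapply(x, unpack_obj)
  } else x
}

#' Save / load a trained CV model
#'
#' Serialises the architecture, parameters, standardisation statistics and
#' output conventions to a portable JSON file at full precision.
#'
#' @param model a \code{deep_lda_cv} or \code{multitask_cv}.
#' @param path file path.
#' @export
save_cv_model <- function(model, path) {
  cls <- class(model)[1L]
  stopifnot(cls %in% c("deep_lda_cv", "multitask_cv"))
  payload <- pack_obj(unclass(model))
  payload$`_class` <- cls
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_cv_model
#' @export
load_cv_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- payload$`_class`
  payload$`_class` <- NULL
  obj <- unpack_obj(payload)
  fix_net <- function(net) {
    net$W <- lapply(net$W, function(w) w)
    net$b <- lapply(net$b, function(b) unlist(b))
    net$widths <- unlist(net$widths)
    class(net) <- "opescv_mlp"
    net
  }
  num <- function(v) if (is.list(v)) unlist(v) else v
  if (!is.null(obj$net)) obj$net <- fix_net(obj$net)
  if (!is.null(obj$encoder)) obj$encoder <- fix_net(obj$encoder)
  if (!is.null(obj$decoder)) obj$decoder <- fix_net(obj$decoder)
  for (f in c("w", "mu", "sd", "affine", "states", "loss_history"))
    if (!is.null(obj[[f]])) obj[[f]] <- num(obj[[f]])
  if (!is.null(obj$meta))
    obj$meta <- as.data.frame(lapply(as.data.frame(
      do.call(rbind, lapply(obj$meta, function(r) r))), unlist),
      stringsAsFactors = FALSE)
  structure(obj, class = cls)
}

# ---------------------------------------------------------------------------
# Pipeline configuration
# ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' Full nested defaults for \code{\link{run_pipeline}}. The OPES blocks
#' use the field's parameter names (BARRIER, STRIDE, SIGMA); the
#' training blocks carry the reference hyperparameters; \code{scale} blocks set
#' the problem sizes (frames, steps), which default to desk-scale values.
#'
#' @return nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("generate", "filter", "train-lda", "sample-opes-1d",
               "label-states", "train-multitask", "sample-opes-2d",
               "fes", "report"),
    output_dir = "opescv-run",
    generate = list(n_frames = 2000L, n_labeled = 2000L,
                    n_reactive = 4000L),
    filter = list(presence_cutoff = 6.0, presence_fraction = 0.5,
                  sd_rule = "max"),
    lda = list(epochs = 150L, learning_rate = 5e-4, l2 = 1e-4,
               sw_reg = 0.05, lorentzian = 40),
    multitask = list(epochs = 150L, learning_rate = 1e-3,
                     steps_per_epoch = 5L, batch_per_state = 250L,
                     batch_reactive = 1000L),
    opes_1d = list(BARRIER = 20, STRIDE = 500L, SIGMA = 0.05,
                   variant = "explore", sigma_min_frac = 0.2,
                   n_steps = 400000L, wall = 1.5, wall_k = 40000),
    opes_2d = list(BARRIER = 20, STRIDE = 250L, SIGMA = 0.25,
                   variant = "standard", sigma_min_frac = 1,
                   n_steps = 1000000L, wall = 7.5, wall_k = 40000),
    fes = list(bins = 60L, bounds = 7.5, n_blocks = 4L,
               latent_bounds = c(-0.35, 1.35)),
    states = list(radius = 0.25, settle = 10L)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, applies the defaults of
#' \code{\link{default_pipeline_config}} for omitted keys, and rejects
#' unknown keys (naming them) so misspellings fail loudly. An empty file
#' yields the full default configuration.
#'
#' @param path YAML file.
#' @return validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_strict(default_pipeline_config(), user, "config")
}

merge_strict <- function(defaults, user, where) {
  if (!is.list(user))
    stop("configuration error: '", where, "' must be a mapping",
         call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("configuration error: unknown key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_strict(defaults[[k]], as.list(user[[k]]),
                                    paste0(where, "$", k))
    } else {
      v <- user[[k]]
      if (is.numeric(defaults[[k]]) && !is.numeric(v))
        stop("configuration error: key ", where, "$", k,
             " must be numeric", call. = FALSE)
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Run the full surrogate analysis pipeline
#'
#' Executes the requested stages in order -- generate the fixtures, filter
#' the candidate descriptors, train the Deep-LDA CV, run 1-D OPES, label
#' states and count transitions, train the multitask CV, run 2-D OPES,
#' estimate the FES and extract barriers -- persisting every artifact under
#' \code{output_dir} and returning a report. Rerunning with the same
#' configuration and seed reproduces the report.
#'
#' @param config a configuration list from \code{\link{load_config}} /
#'   \code{\link{default_pipeline_config}} (optionally modified), or a
#'   path to a YAML file.
#' @return list of class \code{pipeline_report}.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- load_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$output_dir)
  seed <- as.integer(config$seed)
  report <- list(seed = seed, stages = config$stages)
  st <- function(name) name %in% config$stages
  env <- new.env()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }
  if (st("generate")) run_stage("generate", function() {
    env$system <- build_surrogate()
    env$fixture <- make_fixture(seed = seed,
                                n_frames = config$generate$n_frames)
    write_descriptor_table(env$fixture$PRE, file.path(out, "pre.csv"))
    write_descriptor_table(env$fixture$POST, file.path(out, "post.csv"))
  })
  if (st("filter")) run_stage("filter", function() {
    f <- filter_descriptors(env$fixture$PRE, env$fixture$POST,
                            config$filter$presence_cutoff,
                            config$filter$presence_fraction,
                            config$filter$sd_rule)
    env$filtered <- f
    write.csv(f$report, file.path(out, "filter_report.csv"),
              row.names = FALSE)
    report$filter <<- list(n_candidates = nrow(f$report),
                           n_retained = length(f$retained))
  })
  if (st("train-lda")) run_stage("train-lda", function() {
    tabs <- lapply(list(env$fixture$PRE, env$fixture$POST),
                   subset_descriptors, ids = env$filtered$retained)
    tab <- descriptor_table(rbind(tabs[[1]]$values, tabs[[2]]$values),
                            tabs[[1]]$meta,
                            c(tabs[[1]]$labels, tabs[[2]]$labels))
    env$lda <- train_deep_lda(tab, epochs = config$lda$epochs,
                              learning_rate = config$lda$learning_rate,
                              l2 = config$lda$l2, sw_reg = config$lda$sw_reg,
                              lorentzian = config$lda$lorentzian,
                              seed = seed)
    save_cv_model(env$lda, file.path(out, "deep_lda_cv.json"))
    cv <- predict(env$lda, tab)
    report$lda <<- list(
      fisher = env$lda$fisher,
      mean_pre = mean(cv[tab$labels == "PRE"]),
      mean_post = mean(cv[tab$labels == "POST"]))
  })
  if (st("sample-opes-1d")) run_stage("sample-opes-1d", function() {
    cfg <- opes_config(ncv = 1L, barrier = config$opes_1d$BARRIER,
                       stride = config$opes_1d$STRIDE,
                       sigma0 = config$opes_1d$SIGMA,
                       variant = config$opes_1d$variant,
                       sigma_min_frac = config$opes_1d$sigma_min_frac,
                       kT = env$system$kT)
    walls <- wall_spec(-config$opes_1d$wall, config$opes_1d$wall,
                       config$opes_1d$wall_k)
    env$traj1d <- run_opes(env$system, env$lda, cfg, walls,
                           n_steps = config$opes_1d$n_steps, seed = seed)
    write_trajectory_colvar(env$traj1d, file.path(out, "colvar_1d.dat"))
  })
  if (st("label-states")) run_stage("label-states", function() {
    ref <- state_reference(env$system$centers, config$states$radius)
    labs <- assign_states(env$traj1d, ref)
    recs <- count_transitions(labs, settle = config$states$settle)
    env$records <- recs
    write.csv(recs, file.path(out, "transitions.csv"), row.names = FALSE)
    pp <- tryCatch(pathway_preference(recs), error = function(e) NULL)
    report$transitions <<- list(
      n = nrow(recs),
      by_pathway = as.list(table(recs$intermediate)),
      preference_via_int1 = if (is.null(pp)) NA_real_ else pp$fraction)
  })
  if (st("train-multitask")) run_stage("train-multitask", function() {
    fx <- make_multitask_fixture(seed = seed,
                                 n_labeled = config$generate$n_labeled,
                                 n_reactive = config$generate$n_reactive,
                                 system = env$system)
    env$mt <- train_multitask(fx$labeled, fx$reactive,
                              epochs = config$multitask$epochs,
                              learning_rate = config$multitask$learning_rate,
                              steps_per_epoch = config$multitask$steps_per_epoch,
                              batch_per_state = config$multitask$batch_per_state,
                              batch_reactive = config$multitask$batch_reactive,
                              seed = seed)
    save_cv_model(env$mt, file.path(out, "multitask_cv.json"))
    report$multitask <<- list(
      state_centers = apply(env$mt$state_centers, 1, paste,
                            collapse = ", "))
  })
  if (st("sample-opes-2d")) run_stage("sample-opes-2d", function() {
    cfg <- opes_config(ncv = 2L, barrier = config$opes_2d$BARRIER,
                       stride = config$opes_2d$STRIDE,
                       sigma0 = config$opes_2d$SIGMA,
                       variant = config$opes_2d$variant,
                       sigma_min_frac = config$opes_2d$sigma_min_frac,
                       kT = env$system$kT)
    walls <- wall_spec(rep(-config$opes_2d$wall, 2),
                       rep(config$opes_2d$wall, 2), config$opes_2d$wall_k)
    env$traj2d <- run_opes(env$system, env$mt, cfg, walls,
                           n_steps = config$opes_2d$n_steps, seed = seed)
    write_trajectory_colvar(env$traj2d, file.path(out, "colvar_2d.dat"))
  })
  if (st("fes")) run_stage("fes", function() {
    b <- config$fes$bounds
    # display surface over the learned CV space
    fes <- estimate_fes(env$traj2d$cv, env$traj2d$weights,
                        bounds = c(-b, b), bins = config$fes$bins,
                        beta = 1 / env$system$kT)
    env$fes <- fes
    write_fes(fes, file.path(out, "fes.dat"))
    # barriers audited on the strand-progress FES (Jacobian-free)
    eb <- tryCatch(
      barrier_errors(env$traj2d$latent, env$traj2d$weights,
                     bounds = config$fes$latent_bounds,
                     bins = config$fes$bins, beta = 1 / env$system$kT,
                     n_blocks = config$fes$n_blocks,
                     endpoints = env$system$centers),
      error = function(e) NULL)
    if (!is.null(eb))
      write.csv(eb, file.path(out, "barriers.csv"), row.names = FALSE)
    report$barriers <<- eb
  })
  if (st("report")) {
    report$generated <- format(Sys.time(), "%Y-%m-%d")
    jsonlite::write_json(report[setdiff(names(report), "barriers")],
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("opescv pipeline report (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$filter))
    cat("  filter: ", x$filter$n_retained, " of ", x$filter$n_candidates,
        " descriptors retained\n", sep = "")
  if (!is.null(x$lda))
    cat("  Deep-LDA state means: PRE ",
        format(x$lda$mean_pre, digits = 3), ", POST ",
        format(x$lda$mean_post, digits = 3), "\n", sep = "")
  if (!is.null(x$transitions))
    cat("  transitions: ", x$transitions$n, " (fraction via INT1: ",
        format(x$transitions$preference_via_int1, digits = 3), ")\n",
        sep = "")
  if (!is.null(x$barriers)) {
    cat("  barriers (kcal/mol):\n")
    print(x$barriers, row.names = FALSE)
  }
  invisible(x)
}

#' Write a FES grid as a three-column text table
#'
#' @param fes an \code{fes_grid}.
#' @param path output file (columns cv1, cv2, free_energy).
#' @export
write_fes <- function(fes, path) {
  df <- data.frame(cv1 = rep(fes$x, times = length(fes$y)),
                   cv2 = rep(fes$y, each = length(fes$x)),
                   free_energy = as.numeric(fes$F))
  df$free_energy[!is.finite(df$free_energy)] <- NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS cv1 cv2 free_energy", con)
  writeLines(sprintf("%.10g %.10g %.10g", df$cv1, df$cv2, df$free_energy),
             con)
  invisible(path)
}
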