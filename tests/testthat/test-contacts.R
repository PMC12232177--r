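make_defs <- function() {
  rbind(contact_definition("LYS", 10, "A", "primer", 5, 101, "B"),
        contact_definition("ARG", 20, "A", "primer", 4, 101, "B"))
}

test_that("contact distances match hand-computed coordinate geometry", {
  pdb <- write_test_pdb(withr::local_tempfile(fileext = ".pdb"))
  tab <- compute_contact_distances(pdb, make_defs())
  # LYS NZ (1,2,2) -> P (4,0,0); ARG CZ (4,0,3) -> P (4,0,0)
  expect_equal(unname(tab$values[1, 1]), sqrt(9 + 4 + 4), tolerance = 1e-3)
  expect_equal(unname(tab$values[1, 2]), 3.0, tolerance = 1e-3)
})

test_that("multi-model PDBs give one row per frame in file order", {
  pdb <- write_test_pdb(withr::local_tempfile(fileext = ".pdb"), n_models = 3)
  tab <- compute_contact_distances(pdb, make_defs())
  expect_equal(nrow(tab$values), 3L)
  # P shifts +1 Angstrom in x per model: ARG CZ at (4,0,3)
  expect_equal(unname(tab$values[, 2]),
               sqrt((0:2)^2 + 9), tolerance = 1e-3)
})

test_that("anchor atoms are fixed by residue type", {
  expect_error(contact_definition("LYS", 10, "A", "primer", 5, 101, "B",
                                  anchor_atom = "CZ"), "inconsistent")
  expect_error(contact_definition("GLY", 10, "A", "primer", 5, 101, "B"),
               "LYS")
  d <- contact_definition("ARG", 20, "A", "template", 4, 101, "B")
  expect_identical(d$anchor_atom, "CZ")
  expect_identical(d$base_pair_label, "T4")
})

test_that("missing atoms and wrong residues raise resolution errors", {
  pdb <- write_test_pdb(withr::local_tempfile(fileext = ".pdb"))
  bad <- contact_definition("LYS", 99, "A", "primer", 5, 101, "B")
  expect_error(compute_contact_distances(pdb, bad), "resno 99")
  wrong_type <- contact_definition("ARG", 10, "A", "primer", 5, 101, "B")
  expect_error(compute_contact_distances(pdb, wrong_type), "not ARG")
  bad_dna <- contact_definition("LYS", 10, "A", "primer", 5, 500, "B")
  expect_error(compute_contact_distances(pdb, bad_dna), "not found")
})

# small crafted tables with controlled presence/separation behaviour
crafted_tables <- function() {
  meta <- data.frame(
    descriptor_id = c("sep", "ident", "lowpres", "dupA", "dupB"),
    residue_label = c("LYS1", "ARG2", "LYS3", "ARG4", "ARG4"),
    base_pair_label = c("P1", "P2", "P3", "P4", "P4"),
    stringsAsFactors = FALSE)
  n <- 100L
  set.seed(31)
  # 'lowpres': within the 6 A cutoff in exactly 49 of 100 frames, both states
  lp <- c(rep(5, 49), rep(8, 51))
  A <- cbind(sep = rnorm(n, 4, 0.2), ident = rnorm(n, 5, 0.3),
             lowpres = sample(lp), dupA = rnorm(n, 4, 0.2),
             dupB = rnorm(n, 4, 0.5))
  B <- cbind(sep = rnorm(n, 8, 0.2), ident = A[, "ident"],
             lowpres = sample(lp), dupA = rnorm(n, 8, 0.2),
             dupB = rnorm(n, 8, 0.5))
  list(A = descriptor_table(A, meta), B = descriptor_table(B, meta))
}

test_that("the three rules fire in order with the documented criteria", {
  tabs <- crafted_tables()
  f <- filter_descriptors(tabs$A, tabs$B)
  rep <- f$report
  expect_setequal(f$retained, c("sep", "dupA"))
  expect_identical(rep$removing_rule[rep$descriptor_id == "ident"],
                   "separation")
  expect_identical(rep$removing_rule[rep$descriptor_id == "lowpres"],
                   "presence")
  # brute-force presence count: 49/100 frames within cutoff in both states
  expect_equal(rep$presence_a[rep$descriptor_id == "lowpres"], 0.49)
  # dedup keeps the larger rule-(ii) margin within the ARG4-P4 group
  expect_identical(rep$removing_rule[rep$descriptor_id == "dupB"], "dedup")
  expect_gt(rep$margin[rep$descriptor_id == "dupA"],
            rep$margin[rep$descriptor_id == "dupB"])
})

test_that("rejections record the first failing rule", {
  # a column failing presence AND separation must be tagged 'presence'
  meta <- data.frame(descriptor_id = c("both", "keep"),
                     residue_label = c("LYS1", "LYS2"),
                     base_pair_label = c("P1", "P2"),
                     stringsAsFactors = FALSE)
  set.seed(5)
  A <- cbind(both = rnorm(50, 9, 0.1), keep = rnorm(50, 4, 0.1))
  B <- cbind(both = rnorm(50, 9, 0.1), keep = rnorm(50, 5.5, 0.1))
  f <- filter_descriptors(descriptor_table(A, meta),
                          descriptor_table(B, meta))
  expect_identical(f$report$removing_rule, c("presence", "none"))
})

test_that("filtering is idempotent and symmetric in the two states", {
  tabs <- crafted_tables()
  f1 <- filter_descriptors(tabs$A, tabs$B)
  a2 <- subset_descriptors(tabs$A, f1$retained)
  b2 <- subset_descriptors(tabs$B, f1$retained)
  f2 <- filter_descriptors(a2, b2)
  expect_identical(f2$retained, f1$retained)
  f_swap <- filter_descriptors(tabs$B, tabs$A)
  expect_setequal(f_swap$retained, f1$retained)
})

test_that("degenerate and mismatched inputs raise schema errors", {
  tabs <- crafted_tables()
  empty <- descriptor_table(tabs$A$values[0, , drop = FALSE], tabs$A$meta)
  expect_error(filter_descriptors(empty, tabs$B), "empty")
  shuffled <- descriptor_table(tabs$B$values[, c(2:5, 1)],
                               tabs$B$meta[c(2:5, 1), ])
  expect_error(filter_descriptors(tabs$A, shuffled), "schema error")
  expect_error(subset_descriptors(tabs$A, "nope"), "unknown descriptor")
})
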