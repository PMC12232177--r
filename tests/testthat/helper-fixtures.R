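# Shared fixtures, memoized so the expensive trainings and biased runs are
# done once per test session. All generation is seeded and in-code.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_system <- function() memo("system", build_surrogate())

# the packaged two-state candidate pool at reference composition, 5000 frames
# per state (the training-scale setting)
fixture_pool <- function() memo("pool", make_fixture(seed = 1, n_frames = 5000))

filtered_ids <- function() memo("filtered", {
  f <- filter_descriptors(fixture_pool()$PRE, fixture_pool()$POST)
  f$retained
})

# labeled two-state table over the 69 retained descriptors
lda_table <- function() memo("lda_table", {
  pool <- fixture_pool()
  tabs <- lapply(list(pool$PRE, pool$POST), subset_descriptors,
                 ids = filtered_ids())
  descriptor_table(rbind(tabs[[1]]$values, tabs[[2]]$values),
                   tabs[[1]]$meta, c(tabs[[1]]$labels, tabs[[2]]$labels))
})

# Deep-LDA CV trained with the reference hyperparameters
lda_model <- function() memo("lda_model", train_deep_lda(lda_table(), seed = 1))

multitask_fixture <- function() memo("mt_fixture",
  make_multitask_fixture(seed = 1, n_labeled = 5000, n_reactive = 10000))

multitask_model <- function() memo("mt_model", {
  fx <- multitask_fixture()
  train_multitask(fx$labeled, fx$reactive, seed = 1)
})

# pooled 1-D OPES exploration runs on the Deep-LDA CV; transitions are
# productive early in each run (a converged bias floods the corridor), so
# many short runs are pooled
opes1d_records <- function() memo("opes1d_records", {
  sys <- default_system()
  cfg <- opes_config(ncv = 1, barrier = 20, stride = 500, sigma0 = 0.05,
                     kT = sys$kT)
  walls <- wall_spec(-1.5, 1.5, 40000)
  recs <- lapply(11:26, function(sd) {
    tr <- run_opes(sys, lda_model(), cfg, walls, n_steps = 2.5e6, seed = sd)
    cbind(seed = sd, count_transitions(assign_states(tr)))
  })
  do.call(rbind, recs)
})

# quantitative 2-D OPES run on the multitask CV (standard variant, fixed
# kernel bandwidth; settings documented in the methods vignette)
opes2d_run <- function() memo("opes2d_run", {
  sys <- default_system()
  cfg <- opes_config(ncv = 2, barrier = 20, stride = 250, sigma0 = 0.25,
                     kT = sys$kT, variant = "standard", sigma_min_frac = 1)
  walls <- wall_spec(c(-7.5, -7.5), c(7.5, 7.5), 40000)
  run_opes(sys, multitask_model(), cfg, walls, n_steps = 6e6, seed = 21)
})

# a low-barrier variant for equilibrium comparisons (transitions observable
# without bias)
shallow_system <- function() memo("shallow", build_surrogate(
  basin_energies = c(PRE = 0, INT1 = 0.3, INT2 = 0.4, POST = 0),
  saddle_heights = c(1.0, 1.3, 1.5, 1.4),
  diagonal_penalty = 12, kT = 0.616))

sample_fixture_subset <- function(fx, n_per_state) {
  lab <- fx$labeled$labels
  idx <- unlist(lapply(unique(lab), function(s)
    which(lab == s)[seq_len(n_per_state)]))
  list(labeled = descriptor_table(fx$labeled$values[idx, , drop = FALSE],
                                  fx$labeled$meta, lab[idx]),
       labels = lab[idx])
}

sample_frames_for_test <- function(sys, state, n = 800L) {
  opescv:::sample_state_frames(
    sys, state, n, seed = 1000L + match(state, rownames(sys$centers)))
}

# tiny in-code PDB fixture: a lysine, an arginine and one nucleotide with
# hand-placed coordinates (values asserted in tests)
write_test_pdb <- function(path, n_models = 1L) {
  atom <- function(serial, name, res, chain, resno, x, y, z) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, res, chain, resno, x, y, z)
  }
  lines <- character()
  for (m in seq_len(n_models)) {
    off <- (m - 1L) * 1.0  # shift P along x per model
    lines <- c(lines,
      if (n_models > 1L) sprintf("MODEL     %4d", m),
      atom(1, "CA", "LYS", "A", 10, 0, 0, 0),
      atom(2, "NZ", "LYS", "A", 10, 1.0, 2.0, 2.0),
      atom(3, "CA", "ARG", "A", 20, 5, 5, 5),
      atom(4, "CZ", "ARG", "A", 20, 4.0, 0.0, 3.0),
      atom(5, "P",  "DG",  "B", 101, 4.0 + off, 0.0, 0.0),
      if (n_models > 1L) "ENDMDL")
    if (n_models == 1L) break
  }
  writeLines(c(lines, "END"), path)
  path
}
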