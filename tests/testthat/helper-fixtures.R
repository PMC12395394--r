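# Lazily built, memoized fixtures shared across test files. Everything is
# generated in code; tissues are deterministic functions of their arguments.
fixture_store <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_store, inherits = FALSE))
    assign(name, expr, envir = fixture_store)
  get(name, envir = fixture_store, inherits = FALSE)
}

hex_small <- function() memo("hex_small", suppressMessages(make_hexagonal_tissue(20)))

dis_small <- function() memo("dis_small", make_disordered_tissue(24, c(5, 5), seed = 42))

# ordered tissue at the reference size used throughout the 2D experiments
hex_260 <- function() memo("hex_260",
  suppressMessages(make_hexagonal_tissue(260, c(14, 18.6))))

dis_208 <- function(seed) memo(paste0("dis_208_", seed),
  make_disordered_tissue(208, c(14, 15), seed = seed))

# single-junction-seeded ordered run at given (tau, kL), memoized
ordered_run <- function(tau, kL, t_end = 20) {
  memo(sprintf("ordrun_%g_%g_%g", tau, kL, t_end), {
    mp <- mech_params(kL = kL)
    ep <- excit_params(tau_act = tau, tau_ref = tau)
    tis <- seed_activation(hex_260(), "single", NULL, ep)
    run_simulation(tis, mp, ep, t_end = t_end)
  })
}

disordered_run <- function(seed, tau = 1.6, kL = 0.7, t_end = 20) {
  memo(sprintf("disrun_%d_%g_%g", seed, tau, kL), {
    mp <- mech_params(kL = kL)
    ep <- excit_params(tau_act = tau, tau_ref = tau)
    tis <- seed_activation(dis_208(seed), "single", NULL, ep)
    run_simulation(tis, mp, ep, t_end = t_end)
  })
}

# jittered copy of a tissue (deterministic)
jitter_tissue <- function(tissue, amount = 0.01, seed = 7) {
  tissue$pos <- withr::with_seed(seed,
    tissue$pos + matrix(stats::runif(2L * nrow(tissue$pos), -amount, amount),
                        ncol = 2L))
  tissue$pos <- excitissue:::wrap_positions(tissue$pos, tissue$box)
  tissue
}

# minimum-image distance between matching vertices of two tissues
max_vertex_displacement <- function(t1, t2) {
  d <- excitissue:::min_image(t1$pos - t2$pos, t1$box)
  max(sqrt(d[, 1L]^2 + d[, 2L]^2))
}
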