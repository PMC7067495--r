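# Mixed-scenario parametrisation, mutation kernel, two-phase evolutionary
# search and conductance-plane clustering.

test_that("mixture parameters interpolate the two reference modules", {
  ref_cv <- reference_params("cav_bk")
  ref_cs <- reference_params("catsper_nhe")
  m10 <- mixed_parameters(1, 0, derive = FALSE)
  expect_equal(m10$g_cv, ref_cv$g_cv)
  expect_equal(m10$g_bk, ref_cv$g_bk)
  expect_equal(m10$g_cs, 0)
  expect_equal(m10$g_L, ref_cv$g_L)
  expect_equal(m10$delta_C, ref_cv$delta_C)
  m01 <- mixed_parameters(0, 1, derive = FALSE)
  expect_equal(m01$g_cs, ref_cs$g_cs)
  expect_equal(m01$g_cv, 0)
  expect_equal(m01$g_L, ref_cs$g_L)
  expect_equal(m01$delta_C, ref_cs$delta_C)
  half <- mixed_parameters(0.5, 0.5, derive = FALSE)
  expect_equal(half$g_L, (1.94 + 9) / 2)   # 5.47 pS um^-2
  expect_equal(attr(half, "r_g"), 0.5 * 39.9 / (0.5 * 185.16))
  expect_error(mixed_parameters(-0.1, 0.5), "non-negative")
})

test_that("the mutation kernel is lognormal with the stated spread and
           leaves the upstream block untouched", {
  p0 <- mixed_parameters(1, 1, derive = FALSE)
  set.seed(77)
  same <- mutate_params(p0, sd_log = 0)
  expect_identical(unclass(same), unclass(p0))
  lr <- replicate(10000, {
    p1 <- mutate_params(p0, 0.04, derive = FALSE)
    log(p1$g_cv / p0$g_cv)
  })
  se_mean <- 0.04 / sqrt(10000)
  expect_lt(abs(mean(lr)), 3 * se_mean)
  expect_lt(abs(sd(lr) - 0.04), 3 * 0.04 / sqrt(2 * 10000))
  set.seed(78)
  mut <- mutate_params(p0, 0.1, derive = FALSE)
  for (nm in c("R_T", "r1", "r2", "k_H", "alpha_kn", "g_kn", "g_hc", "h3"))
    expect_identical(mut[[nm]], p0[[nm]])
  expect_false(identical(mut$g_cv, p0$g_cv))
  ## signed parameters keep their sign
  expect_lt(mut$v2, 0)
})

test_that("the default seed grid has 21 x 21 = 441 weight vectors", {
  g <- seed_grid()
  expect_equal(nrow(g), 441)
  expect_equal(sort(unique(g$theta_cv)), c(1e-4, seq(0.1, 2, 0.1)))
})

surrogate_eval <- function(params) {
  ft <- c(T_bar = 0.5, b_A = -0.05, b_T = 0.04, n_spikes = 8)
  list(features = ft, selected = params$g_cv + params$g_cs > 100)
}

test_that("the two-phase evolution is deterministic for a fixed seed and
           respects its budgets", {
  g <- seed_grid(c(1e-4, 0.5, 1))
  pop1 <- evolve_population(g, 12, 12, evaluate_fn = surrogate_eval,
                            seed = 42)
  pop2 <- evolve_population(g, 12, 12, evaluate_fn = surrogate_eval,
                            seed = 42)
  expect_identical(as.data.frame(pop1), as.data.frame(pop2))
  expect_equal(nrow(pop1), 9 + 12 + 12)
  expect_equal(sum(pop1$phase == "seed"), 9)
  expect_equal(sum(pop1$phase == "neutral"), 12)
  expect_equal(sum(pop1$phase %in% c("selected", "unselected")), 12)
  ## phase-2 parents are selected vectors only
  ph2 <- pop1[pop1$phase %in% c("selected", "unselected"), ]
  expect_true(all(pop1$selected[ph2$parent]))
  ## every vector flagged selected satisfies the predicate on re-evaluation
  pl <- attr(pop1, "params")
  for (i in pop1$id[pop1$selected])
    expect_true(surrogate_eval(pl[[i]])$selected)
})

test_that("a zero budget returns the seed grid only, and zero selected
           vectors skip phase 2 with a warning", {
  g <- seed_grid(c(1e-4, 0.5))
  pop <- evolve_population(g, 0, 0, evaluate_fn = surrogate_eval, seed = 1)
  expect_equal(nrow(pop), 4)
  expect_true(all(pop$phase == "seed"))
  never <- function(params) list(features = c(T_bar = NA, b_A = NA,
                                              b_T = NA, n_spikes = 0),
                                 selected = FALSE)
  expect_warning(
    evolve_population(seed_grid(c(1e-4, 0.5)), 2, 5, evaluate_fn = never,
                      seed = 1),
    "skipped")
})

test_that("clustering separates distinct conductance blobs and is invariant
           to input order", {
  set.seed(55)
  mk <- function(g_cv, g_cs, n, sel) data.frame(
    id = seq_len(n), g_cv = g_cv * exp(rnorm(n, 0, 0.05)),
    g_cs = g_cs * exp(rnorm(n, 0, 0.05)), selected = sel)
  pop <- rbind(mk(185, 0.004, 20, TRUE), mk(0.02, 39.9, 20, FALSE))
  pop$id <- seq_len(nrow(pop))
  cl <- cluster_population(pop)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:20])), 1)
  expect_equal(length(unique(cl$cluster[21:40])), 1)
  perm <- sample(nrow(pop))
  cl2 <- cluster_population(pop[perm, ])
  expect_equal(cl2$cluster[order(pop$id[perm])], cl$cluster)
  summ <- attr(cl, "cluster_summary")
  expect_equal(summ$fraction_selected[summ$mean_g_cv > 100], 1)
})

test_that("module necessity: each reference module depends on its own
           calcium pathway only", {
  eval10 <- function(params) evaluate_vector(params, S0 = 10,
                                             end_time = 22)
  nec_cs <- module_necessity(mixed_parameters(0, 1), evaluate_fn = eval10)
  expect_equal(nec_cs$catsper, "essential")
  expect_match(nec_cs$cav_bk, "irrelevant|modulatory")
  nec_cv <- module_necessity(mixed_parameters(1, 0),
                             evaluate_fn = function(p)
                               evaluate_vector(p, S0 = 25, end_time = 22))
  expect_match(nec_cv$catsper, "irrelevant|modulatory")
  ## all calcium conductances cancelled: degenerate vector
  dead <- mixed_parameters(1, 1, derive = FALSE)
  dead$g_cv <- dead$g_cs <- dead$g_bk <- 0
  dead <- derive_parameters(dead, module_config("mixed", 1, 1))
  nec0 <- module_necessity(dead, evaluate_fn = eval10)
  expect_equal(nec0$catsper, "degenerate")
  expect_equal(nec0$cav_bk, "degenerate")
})

test_that("populations round-trip through the JSON-lines checkpoint", {
  pop <- evolve_population(seed_grid(c(1e-4, 1)), 3, 0,
                           evaluate_fn = surrogate_eval, seed = 2)
  f <- tempfile(fileext = ".jsonl")
  write_population(pop, f)
  back <- read_population(f)
  expect_equal(nrow(back), nrow(pop))
  expect_equal(back$g_cv, pop$g_cv, tolerance = 1e-12)
  expect_equal(attr(back, "params")[[3]]$g_cs,
               attr(pop, "params")[[3]]$g_cs, tolerance = 1e-12)
  unlink(f)
})
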