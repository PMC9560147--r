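# Shared fixtures, built once per test run and memoised.

# 2 panels, one distance-2 and one distance-3 target per half: small enough
# for the straight-loop oracle, but with two targets per half so memory
# formation is genuinely required (unlike the mini task).
micro_geometry <- function()
  panel_geometry(n_panels = 2,
                 offsets = data.frame(dist = c(2, 3), ox = c(1, 1),
                                      oy = c(1, 2)))

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

get_task <- function(name = c("mini", "micro", "reduced", "default")) {
  name <- match.arg(name)
  memo(paste0("task_", name), build_task(switch(name,
    mini = mini_geometry(), micro = micro_geometry(),
    reduced = reduced_geometry(), default = default_geometry())))
}

get_policy <- function(task_name, beta1, beta2) {
  memo(sprintf("pol_%s_%g_%g", task_name, beta1, beta2),
       solve_policy(get_task(task_name), beta1, beta2))
}

# capacity grid on the reduced task shared by regression / cohort tests
REDUCED_BETAS <- c(5, 50, 500)
get_reduced_grid <- function()
  memo("grid_reduced",
       capacity_grid(get_task("reduced"), REDUCED_BETAS, REDUCED_BETAS))

# uniform (information-free) policy for a task, as a policy object
uniform_policy <- function(task, beta1 = 1, beta2 = 1) {
  M <- task$n_m; nA <- task$n_a
  pol <- structure(list(
    beta1 = beta1, beta2 = beta2,
    p_m_given_s1 = matrix(1 / M, M, M), p_m = rep(1 / M, M),
    p_a_given_ms2 = array(1 / nA, c(nA, M, task$n_s2)),
    p_a = rep(1 / nA, nA),
    converged = TRUE, n_iter = 0L, residual = 0,
    task_dims = c(n_s1 = task$n_s1, n_a = task$n_a, n_s2 = task$n_s2)),
    class = "agent_policy")
  pol
}

# a 12-condition information profile assembled directly (design-matrix
# fixture for regression tests that need the full condition count)
synthetic_profile_12 <- function(I1, I2, hypothesis = "H1_prospective",
                                 beta1 = 500, beta2 = 500, EU = 1) {
  conds <- expand.grid(cS = c(2, 3, 4), cT = c("1", "11", "2", "4"),
                       stringsAsFactors = FALSE)[, 2:1]
  conds <- conds[order(match(conds$cT, c("1", "11", "2", "4")), conds$cS), ]
  rownames(conds) <- NULL
  prof <- data.frame(conds, I1_bits = I1, I2_bits = I2,
                     NTS = nts_multiplier(conds$cT))
  structure(prof, hypothesis = hypothesis, beta1 = beta1, beta2 = beta2,
            EI1 = mean(I1), EI2 = mean(I2), EU = EU, converged = TRUE,
            class = c("information_profile", "data.frame"))
}
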