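# shared helpers for building small parameter sets and series in tests

random_params <- function(n, seed = 42) {
  # valid sets with net rate r >= -0.5 so trajectories stay O(0.1) or
  # larger over t* in [0, 5] and relative comparisons are meaningful
  set.seed(seed)
  replicate(n, simplify = FALSE, {
    k <- runif(1, 0.05, 1)
    kg_max <- max(0, 1.5 / k - 1)
    kg <- runif(1, 0, min(kg_max, 5))
    g <- runif(1, 0.5, 2)
    model_params(T_days = runif(1, 2, 15), k_star = k,
                 k_kill = kg / g, g = g, n0 = runif(1, 0.2, 3))
  })
}

mean_series <- function(group, day, volume, sem = NA_real_) {
  tumor_series(group, data.frame(animal_id = "mean", day = day,
                                 volume = volume, sem = sem))
}

# noiseless normalised series generated from known parameters
model_series <- function(group, p, days = c(0, 5, 7, 11, 15, 19, 23)) {
  v <- logistic_solution(p, days / p$T_days)$n_star
  tumor_series(group, data.frame(animal_id = "mean", day = days,
                                 volume = v, sem = NA_real_),
               normalized = TRUE)
}
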