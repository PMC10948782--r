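# shared small fixtures, built once per test run

fast_sampler <- function(chains = 2, iter = 3000) {
  sampler_control(chains = chains, adapt = 300, burnin = 500,
                  iter = iter, thin = 2)
}

tiny_config <- function(n_persons = 8, ...) {
  study_config(n_persons = n_persons,
               sampler = fast_sampler(),
               selection = list(repetitions = 15, folds = 5), ...)
}

# cached small study bundle used across test files
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(tiny_config(), seed = 11)
    cache
  }
})

# brute-force reading-by-reading glycemic summary, kept deliberately naive
# as an independent oracle for glycemic_profile()
oracle_profile <- function(g) {
  n <- length(g)
  m <- sum(g) / n
  ss <- 0
  for (x in g) ss <- ss + (x - m)^2
  s <- sqrt(ss / (n - 1))
  cnt <- c(inr = 0, b70 = 0, b54 = 0, a180 = 0, a250 = 0)
  for (x in g) {
    if (x >= 70 && x <= 180) cnt["inr"] <- cnt["inr"] + 1
    if (x < 70) cnt["b70"] <- cnt["b70"] + 1
    if (x < 54) cnt["b54"] <- cnt["b54"] + 1
    if (x > 180) cnt["a180"] <- cnt["a180"] + 1
    if (x > 250) cnt["a250"] <- cnt["a250"] + 1
  }
  list(mean = m, sd = s, cv = 100 * s / m, pct = 100 * cnt / n)
}

make_session_row <- function(person_id = "p001", session_index = 1L,
                             start = as.POSIXct("2023-03-03 10:00:00",
                                                tz = "UTC")) {
  data.frame(person_id = person_id, session_index = session_index,
             start_time = start, stringsAsFactors = FALSE)
}
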