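# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# state is untouched. `seed = NULL` uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

logistic <- function(x) stats::plogis(x)

# Expected values of the two offers, by side and by risk category.
# Safe offers pay with certainty; risky offers pay volume with prob p.
offer_evs <- function(trials) {
  ev_safe <- trials$safe_volume
  ev_risky <- trials$risky_prob * trials$risky_volume
  right_is_safe <- trials$safe_side == "right"
  list(
    ev_safe = ev_safe,
    ev_risky = ev_risky,
    ev_left = ifelse(right_is_safe, ev_risky, ev_safe),
    ev_right = ifelse(right_is_safe, ev_safe, ev_risky)
  )
}

stopifnot_trials <- function(trials, need_choices = TRUE) {
  base <- c("trial_index", "safe_side", "safe_volume", "risky_volume",
            "risky_prob")
  chc <- c("choice_side", "chose_safe", "rewarded", "reward_volume")
  need <- if (need_choices) c(base, chc) else base
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trials table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (need_choices && anyNA(trials$choice_side)) {
    stop("trials table has unset choices; run simulate_agent() first")
  }
  invisible(trials)
}
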