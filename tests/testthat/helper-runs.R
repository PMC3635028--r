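## Shared, lazily computed network runs. The heavy simulations are run once
## per test session and cached in this environment; every run uses a small
## trial count and a 2.1 s trial (1 s settling + 1 s analysis epoch) so the
## whole suite stays fast.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(variant, n_trials = 10, duration = 2100,
                       record_v = FALSE, wiring_seed = 1, odor = NULL,
                       seed = 7) {
  if (is.null(odor)) odor <- al_odor(1)
  key <- paste(variant, n_trials, duration, record_v, wiring_seed,
               odor$seed, paste(odor$pn, collapse = ","), seed, sep = "|")
  if (is.null(.run_cache[[key]])) {
    cfg <- al_config(variant, al_wiring(wiring_seed), odor,
                     n_trials = n_trials, duration = duration,
                     seed = seed, record_v = record_v)
    .run_cache[[key]] <- run_experiment(cfg)
  }
  .run_cache[[key]]
}

analysis_epoch <- c(1000, 2000)

## brute-force O(n_spikes^2) oracle for the windowed conditional
brute_cjp <- function(fx, i, targets, w, epoch) {
  num <- 0; den <- 0
  for (tr in fx$trials) {
    for (t in tr$pn[[i]]) {
      if (t < epoch[1] || t > epoch[2]) next
      den <- den + 1
      ok <- all(vapply(targets, function(j)
        any(abs(tr$pn[[j]] - t) <= w / 2 + 1e-12), logical(1)))
      if (ok) num <- num + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}
options(testthat.progress.max_fails = Inf)
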