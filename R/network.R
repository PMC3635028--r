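## Random wiring diagram and the seven network variants.

#' Build the random wiring diagram
#'
#' Draws the four directed adjacency structures with cell-type-specific
#' Bernoulli connection probabilities: PN→PN and PN→LN at 0.1, LN→LN at
#' 0.25, LN→PN at 0.15. The slow inhibitory synapses share the LN→PN
#' adjacency, so every PN receives fast and slow inhibition from the same
#' LNs. Self-connections are excluded for the PN→PN and LN→LN draws.
#' The same seed always regenerates the identical diagram.
#'
#' @param seed integer wiring seed.
#' @param params model parameters (cell counts and probabilities).
#' @return An object of class `al_wiring`: a list of edge matrices
#'   (`pn_pn`, `pn_ln`, `ln_ln`, `ln_pn`, two columns `pre`/`post`,
#'   1-based) plus the seed and probabilities used.
#' @examples
#' w <- al_wiring(seed = 1)
#' nrow(w$pn_pn) / (90 * 89)   # close to 0.1
#' @export
al_wiring <- function(seed, params = al_params()) {
  np <- params$net
  draw <- function(n_pre, n_post, p, no_self) {
    m <- matrix(stats::runif(n_pre * n_post) < p, n_pre, n_post)
    if (no_self) diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE)
    cbind(pre = unname(idx[, 1]), post = unname(idx[, 2]))
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  w <- list(
    n_pn = np$n_pn, n_ln = np$n_ln,
    pn_pn = draw(np$n_pn, np$n_pn, np$p_pnpn, TRUE),
    pn_ln = draw(np$n_pn, np$n_ln, np$p_pnln, FALSE),
    ln_ln = draw(np$n_ln, np$n_ln, np$p_lnln, TRUE),
    ln_pn = draw(np$n_ln, np$n_pn, np$p_lnpn, FALSE),
    seed = as.integer(seed),
    p = c(pn_pn = np$p_pnpn, pn_ln = np$p_pnln,
          ln_ln = np$p_lnln, ln_pn = np$p_lnpn)
  )
  class(w) <- "al_wiring"
  w
}

.save_seed <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.al_wiring <- function(x, ...) {
  cat("Antennal-lobe wiring diagram (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  %d PNs, %d LNs\n", x$n_pn, x$n_ln))
  for (nm in c("pn_pn", "pn_ln", "ln_ln", "ln_pn")) {
    cat(sprintf("  %-6s %4d edges (p = %.2f)\n",
                sub("_", "->", nm), nrow(x[[nm]]), x$p[[nm]]))
  }
  cat("  slow inhibitory synapses share the ln->pn adjacency\n")
  invisible(x)
}

#' Effective conductance table for a network variant
#'
#' Scales the maximal GABA conductances (both LN→PN and LN→LN by default)
#' by the variant's `gaba_scale` and the slow conductance by `slow_scale`,
#' leaving all other conductances and the wiring untouched — so a neuron of
#' a given index has identical afferents and efferents in every variant.
#'
#' @param variant a variant label or the result of [al_variant()].
#' @param params model parameters.
#' @param scale_lnln_gaba logical; also scale LN→LN GABA (default TRUE).
#'   Exposed for sensitivity checks on whether GABA scaling is restricted
#'   to the LN→PN projection.
#' @return Named list of the five effective maximal conductances.
#' @examples
#' apply_variant("NG")$g_gaba_lnpn   # 0
#' apply_variant("NS")$g_slow_lnpn   # 0
#' @export
apply_variant <- function(variant, params = al_params(),
                          scale_lnln_gaba = TRUE) {
  if (is.character(variant)) variant <- al_variant(variant)
  s <- params$syn
  list(
    g_nach_pnpn = s$g_nach_pnpn,
    g_nach_pnln = s$g_nach_pnln,
    g_gaba_lnln = s$g_gaba_lnln *
      (if (scale_lnln_gaba) variant$gaba_scale else 1),
    g_gaba_lnpn = s$g_gaba_lnpn * variant$gaba_scale,
    g_slow_lnpn = s$g_slow_lnpn * variant$slow_scale
  )
}

#' Write / read a wiring diagram as an edge-list text file
#'
#' One directed edge per line (`pre_type pre_index post_type post_index`),
#' preceded by header comments carrying the seed and connection
#' probabilities, so a stored diagram can be reloaded bit-identically.
#'
#' @param wiring an `al_wiring` object.
#' @param path file path.
#' @return `write_wiring` returns `path` invisibly; `read_wiring` returns an
#'   `al_wiring` object.
#' @export
write_wiring <- function(wiring, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# al_wiring seed=%d n_pn=%d n_ln=%d", wiring$seed,
            wiring$n_pn, wiring$n_ln),
    sprintf("# p pn_pn=%g pn_ln=%g ln_ln=%g ln_pn=%g",
            wiring$p[["pn_pn"]], wiring$p[["pn_ln"]],
            wiring$p[["ln_ln"]], wiring$p[["ln_pn"]])), con)
  for (nm in c("pn_pn", "pn_ln", "ln_ln", "ln_pn")) {
    types <- strsplit(nm, "_")[[1]]
    e <- wiring[[nm]]
    if (nrow(e)) {
      writeLines(sprintf("%s %d %s %d", toupper(types[1]), e[, "pre"],
                         toupper(types[2]), e[, "post"]), con)
    }
  }
  invisible(path)
}

#' @rdname write_wiring
#' @export
read_wiring <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getnum <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[0-9.eE+-]+"), hdr))
    as.numeric(sub(paste0(key, "="), "", m[m != ""][1]))
  }
  parts <- do.call(rbind, strsplit(body, " ", fixed = TRUE))
  pre_t <- parts[, 1]; post_t <- parts[, 3]
  pre <- as.integer(parts[, 2]); post <- as.integer(parts[, 4])
  pick <- function(a, b) {
    k <- pre_t == a & post_t == b
    cbind(pre = pre[k], post = post[k])
  }
  w <- list(
    n_pn = as.integer(getnum("n_pn")), n_ln = as.integer(getnum("n_ln")),
    pn_pn = pick("PN", "PN"), pn_ln = pick("PN", "LN"),
    ln_ln = pick("LN", "LN"), ln_pn = pick("LN", "PN"),
    seed = as.integer(getnum("seed")),
    p = c(pn_pn = getnum("pn_pn"), pn_ln = getnum("pn_ln"),
          ln_ln = getnum("ln_ln"), ln_pn = getnum("ln_pn"))
  )
  class(w) <- "al_wiring"
  w
}
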