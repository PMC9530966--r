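# Internal helpers shared across modules.

# Linear predictor from a named coefficient vector and a named list/data.frame
# of features.  Coefficient names absent from `features` must be "intercept";
# feature names absent from `coefs` contribute nothing.  Keeps the DGP and the
# enumeration oracle on one set of formulas.
lin_pred <- function(coefs, features, n) {
  stopifnot(is.numeric(coefs), !is.null(names(coefs)))
  lp <- rep(0, n)
  for (nm in names(coefs)) {
    if (nm == "intercept") {
      lp <- lp + coefs[[nm]]
    } else if (!is.null(features[[nm]])) {
      lp <- lp + coefs[[nm]] * features[[nm]]
    }
    # a coefficient naming a feature the state does not carry is an error:
    # silent zeros here would hide DGP misconfiguration
    if (nm != "intercept" && is.null(features[[nm]])) {
      stop("coefficient '", nm, "' has no matching state variable", call. = FALSE)
    }
  }
  lp
}

# Derived substream seed for (master seed, day, draw kind).  Each substream is
# drawn for all patients at once, so patient i's deviates do not change when
# n_patients grows: earlier patients keep their trajectories.
substream_seed <- function(seed, day, kind) {
  base <- (abs(as.integer(seed)) %% 1000000L) * 1009L
  (base + day * 131L + kind) %% 2147483647L
}

# k uniforms per patient from one stream, interleaved per patient: row j of
# the result is draw kind j.  Patient i consumes k consecutive deviates, so
# the first patients' draws are unchanged when n grows, and the draw kinds
# within a day come from a single well-equidistributed stream rather than
# nearby-seeded streams.
sub_runif_block <- function(n, k, seed, day) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, day, 0L))
  matrix(stats::runif(n * k), nrow = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coefficients must be finite, except that an intercept of -Inf is allowed
# as an explicit off switch (a process that never fires).
assert_finite_coefs <- function(x, what) {
  v <- unlist(x)
  nm <- names(v) %||% rep("", length(v))
  ok <- is.finite(v) | (grepl("intercept", nm) & !is.na(v) & v == -Inf)
  if (!all(ok)) stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}
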