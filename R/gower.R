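#' Gower distances between samples of a mixed-type table
#'
#' Computes the general similarity coefficient of Gower between all sample
#' pairs and returns distances `d = 1 - s`. Per variable `k`, the similarity
#' score is:
#' * qualitative (nominal/binary): 1 if the two samples agree, 0 otherwise;
#' * quantitative: `1 - |x_i - x_j| / R_k`, with `R_k` the observed range;
#' * ordinal (Podani's extension): `1 - |r(x_i) - r(x_j)| / (max r - min r)`,
#'   where `r` are midranks of the observed values.
#'
#' The overall similarity is the weighted mean of the scores over the
#' variables comparable for the pair: a variable with a missing value on
#' either side is skipped (availability indicator `delta = 0`), and weights
#' `w_k` from the spec rescale each variable's contribution. A degenerate
#' variable (zero range, or a single observed ordinal rank) carries no
#' information and is skipped for every pair, with a warning.
#'
#' @param data Samples-by-variables data frame; at most one column absent from
#'   `spec` is treated as the sample identifier.
#' @param spec A [mixed_spec()]; if `NULL`, scales are inferred from column
#'   classes and all weights are 1.
#' @return A [distance_matrix()] over samples (`method = "gower"`), entries in
#'   `[0, 1]`.
#' @references Gower (1971) Biometrics 27:857-871; Podani (1999) Taxon
#'   48:331-340.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   q = c(1, 3, 5), f = factor(c("a", "a", "b"))
#' )
#' gower_dist(d)
gower_dist <- function(data, spec = NULL) {
  cm <- compile_mixed(data, spec)
  if (cm$n < 2) stop("need at least 2 samples", call. = FALSE)
  n <- cm$n
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (v in cm$vars) {
    if (v$weight == 0) next
    sc <- gower_scores(v)
    if (is.null(sc)) next # degenerate variable: delta = 0 everywhere
    avail <- !is.na(sc)
    sc[!avail] <- 0
    num <- num + v$weight * sc
    den <- den + v$weight * avail
  }
  off <- upper.tri(den)
  if (any(den[off] == 0)) {
    idx <- which(den == 0 & off, arr.ind = TRUE)[1, ]
    stop(
      "no comparable variable for sample pair (",
      cm$ids[idx[1]], ", ", cm$ids[idx[2]], ")",
      call. = FALSE
    )
  }
  s <- num / den
  s[den == 0] <- 1 # only possible on the diagonal after the check above
  d <- 1 - s
  d <- pmin(pmax(d, 0), 1)
  diag(d) <- 0
  dimnames(d) <- list(cm$ids, cm$ids)
  new_mixed_matrix((d + t(d)) / 2, "distance", "samples", "gower")
}

# Per-variable score matrix; NA where delta = 0; NULL when degenerate.
gower_scores <- function(v) {
  x <- v$x
  if (v$scale == "quantitative") {
    r <- suppressWarnings(diff(range(x, na.rm = TRUE)))
    if (!is.finite(r) || r == 0) {
      warning("variable '", v$name, "' is degenerate (zero range); skipped", call. = FALSE)
      return(NULL)
    }
    return(1 - abs(outer(x, x, "-")) / r)
  }
  if (v$scale == "ordinal") {
    rk <- rep(NA_real_, length(x))
    ok <- !is.na(x)
    rk[ok] <- rank(as.integer(x[ok])) # midranks over observed values
    span <- suppressWarnings(diff(range(rk, na.rm = TRUE)))
    if (!is.finite(span) || span == 0) {
      warning("variable '", v$name, "' is degenerate (single observed rank); skipped",
        call. = FALSE
      )
      return(NULL)
    }
    return(1 - abs(outer(rk, rk, "-")) / span)
  }
  # nominal / binary
  obs <- unique(x[!is.na(x)])
  if (length(obs) < 2) {
    warning("variable '", v$name, "' is degenerate (single observed category); skipped",
      call. = FALSE
    )
    return(NULL)
  }
  xi <- as.integer(x)
  eq <- outer(xi, xi, "==") * 1
  eq[is.na(x), ] <- NA
  eq[, is.na(x)] <- NA
  eq
}
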