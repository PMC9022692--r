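#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# counter-based seed splitting: independent, order-insensitive substreams
# derived from one master seed; always < 2^31 - 1
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 2147483629 +
                1000003 * as.numeric(index)) %% 2147483629) + 1L
}

#' Age band labels used throughout the package
#'
#' Five-year bands 40-44 ... 75-79 plus an open 80+ band, matching the
#' age-stratified eligibility strata.
#' @return character vector of band labels.
#' @export
age_band_labels <- function() {
  c(paste(seq(40, 75, 5), seq(44, 79, 5), sep = "-"), "80+")
}

#' Assign ages to 5-year bands
#'
#' @param age numeric vector of ages (years).
#' @return factor with levels [age_band_labels()].
#' @export
age_band <- function(age) {
  stopifnot(is.numeric(age))
  lab <- age_band_labels()
  idx <- pmin(floor((age - 40) / 5) + 1, length(lab))
  if (any(age < 40, na.rm = TRUE)) stop("age below 40 has no band")
  factor(lab[idx], levels = lab)
}

weighted_total <- function(w) sum(as.numeric(w))

clip01 <- function(x) pmin(pmax(x, 0), 1)

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints in
# run manifests (no external digest dependency). Arithmetic kept in doubles
# with explicit 16-bit splits to stay exact (R has no unsigned 32-bit type).
fnv1a <- function(x) {
  mulmod32 <- function(a, b) {
    lo <- a %% 65536
    hi <- a %/% 65536
    ((lo * b) %% 4294967296 + ((hi * b) %% 65536) * 65536) %% 4294967296
  }
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- h %/% 256 * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

stop_config <- function(...) {
  stop(structure(class = c("statinpolicy_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
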