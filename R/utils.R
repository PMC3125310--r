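# Small shared helpers: seeded evaluation, rounding convention, checksums.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

#' Round to whole minutes, half up
#'
#' Converts seconds to whole minutes using the round-half-up convention
#' (e.g. 770 s = 12.83 min rounds to 13; 750 s = 12.5 min rounds to 13).
#' This is the convention used everywhere driving times are displayed in
#' minutes, so model minutes are comparable with ambulance log minutes.
#'
#' @param seconds numeric vector of nonnegative durations in seconds.
#' @return integer vector of minutes.
#' @export
#' @examples
#' seconds_to_minutes(c(780, 770, 750))
seconds_to_minutes <- function(seconds) {
  stopifnot(is.numeric(seconds))
  as.integer(floor(seconds / 60 + 0.5))
}

round_half_up <- function(x) floor(x + 0.5)

# Deterministic summary fingerprint of a discretized layer: enough to detect
# that a saved driving-time table and a loaded network do not correspond.
# (Not cryptographic; a content summary in the spirit of a schema version.)
dlayer_fingerprint <- function(dlayer) {
  p <- dlayer$parts
  n <- dlayer$nodes
  sprintf(
    "mcidss-net:%d:%d:%.4f:%.4f:%.4f:%.4f",
    nrow(p), nrow(n),
    sum(p$length_m), sum(p$speed_kmh),
    sum(n$x) + sum(n$y),
    sum(p$cx) + sum(p$cy)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse "HH:MM" (24 h) into minutes after midnight; NA passes through.
parse_clock <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & nzchar(trimws(as.character(x)))
  if (!any(ok)) return(out)
  s <- trimws(as.character(x[ok]))
  m <- regmatches(s, regexec("^([0-9]{1,2}):([0-9]{2})$", s))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed clock time(s): ", paste(unique(s[bad]), collapse = ", "),
         call. = FALSE)
  }
  hh <- as.numeric(vapply(m, `[`, "", 2L))
  mm <- as.numeric(vapply(m, `[`, "", 3L))
  if (any(hh > 23 | mm > 59)) {
    stop("clock time out of range: ",
         paste(unique(s[hh > 23 | mm > 59]), collapse = ", "), call. = FALSE)
  }
  out[ok] <- hh * 60 + mm
  out
}
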