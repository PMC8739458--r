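# Internal helpers shared across modules.

# Parse ISO-8601 datetimes to POSIXct in UTC. Accepts "...Z", "...+hh:mm" /
# "...+hhmm" offsets, or bare "YYYY-mm-ddTHH:MM:SS" (assumed UTC). Vectorised;
# unparseable strings become NA.
parse_iso_dt <- function(x) {
  x <- as.character(x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  if (length(x) == 0) return(out)
  z <- grepl("Z$", x)
  out[z] <- as.POSIXct(sub("Z$", "", x[z]),
                       format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  off <- !z & grepl("[+-][0-9]{2}:?[0-9]{2}$", x)
  if (any(off)) {
    # strip the colon inside the offset so %z applies
    xo <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x[off])
    parsed <- as.POSIXct(xo, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
    out[off] <- parsed
  }
  bare <- !z & !off
  out[bare] <- as.POSIXct(x[bare], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out
}

# Format POSIXct as ISO-8601 UTC with trailing Z; NA -> NA.
format_iso_dt <- function(x) {
  ifelse(is.na(x), NA_character_,
         format(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

# Serialise a double so that it survives text round trips bit-exactly.
format_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

# Strict numeric coercion: returns NA for anything that is not a plain
# finite number (never coerces text like "n/a" to 0).
as_num_strict <- function(x) {
  suppressWarnings(v <- as.numeric(x))
  v[!is.finite(v)] <- NA_real_
  v
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

`%na%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
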