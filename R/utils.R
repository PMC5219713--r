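# Internal helpers: numeric rendering, calendar arithmetic, XML escaping.

# Days from civil date to the 1970-01-01 origin, proleptic Gregorian
# (Hinnant's algorithm; exact over the whole double-safe range).
days_from_civil <- function(y, m, d) {
  y <- y - (m <= 2)
  era <- floor(y / 400)
  yoe <- y - era * 400
  doy <- floor((153 * (m + ifelse(m > 2, -3, 9)) + 2) / 5) + d - 1
  doe <- yoe * 365 + floor(yoe / 4) - floor(yoe / 100) + doy
  era * 146097 + doe - 719468
}

civil_from_days <- function(z) {
  z <- z + 719468
  era <- floor(z / 146097)
  doe <- z - era * 146097
  yoe <- floor((doe - floor(doe / 1460) + floor(doe / 36524) - floor(doe / 146096)) / 365)
  y <- yoe + era * 400
  doy <- doe - (365 * yoe + floor(yoe / 4) - floor(yoe / 100))
  mp <- floor((5 * doy + 2) / 153)
  d <- doy - floor((153 * mp + 2) / 5) + 1
  m <- mp + ifelse(mp < 10, 3, -9)
  list(year = y + (m <= 2), month = m, day = d)
}

# Offset (in days) of the SPSS epoch 1582-10-14 from the Unix origin.
SPSS_EPOCH_DAYS <- -141428  # days_from_civil(1582, 10, 14)

# Shortest decimal literal that parses back to exactly the same double.
# No exponent notation below 10^15 in magnitude. Vectorised: integral
# values take a fast path, the rest resolve in at most 17 sprintf passes.
render_double <- function(x) {
  out <- rep(NA_character_, length(x))
  idx <- which(!is.na(x))
  if (!length(idx)) return(out)
  v <- x[idx]
  res <- character(length(v))
  inf <- !is.finite(v)
  if (any(inf)) res[inf] <- as.character(v[inf])
  integral <- !inf & v == trunc(v) & abs(v) < 1e15
  if (any(integral)) res[integral] <- sprintf("%.0f", v[integral])
  todo <- which(!inf & !integral)
  for (d in 1:17) {
    if (!length(todo)) break
    s <- sprintf("%.*g", d, v[todo])
    hit <- as.numeric(s) == v[todo]
    res[todo[hit]] <- s[hit]
    todo <- todo[!hit]
  }
  needs_fix <- grepl("[eE]", res) & abs(v) < 1e15 & !inf
  if (any(needs_fix))
    res[needs_fix] <- vapply(res[needs_fix], expand_exponent, character(1),
                             USE.NAMES = FALSE)
  out[idx] <- res
  out
}

# "1.23e+05" -> "123000"; "1.5e-03" -> "0.0015". Plain string arithmetic so
# no precision is lost re-formatting.
expand_exponent <- function(s) {
  parts <- strsplit(tolower(s), "e", fixed = TRUE)[[1]]
  mant <- parts[1]
  exp <- as.integer(parts[2])
  neg <- startsWith(mant, "-")
  if (neg) mant <- substring(mant, 2)
  dot <- regexpr(".", mant, fixed = TRUE)
  if (dot > 0) {
    frac <- nchar(mant) - dot
    digits <- sub(".", "", mant, fixed = TRUE)
  } else {
    frac <- 0L
    digits <- mant
  }
  point <- nchar(digits) - frac + exp  # digits before the decimal point
  out <- if (point <= 0) {
    paste0("0.", strrep("0", -point), digits)
  } else if (point >= nchar(digits)) {
    paste0(digits, strrep("0", point - nchar(digits)))
  } else {
    paste0(substr(digits, 1, point), ".", substring(digits, point + 1))
  }
  out <- sub("\\.?0+$", "", out)          # trim trailing fractional zeros
  if (out == "" || out == "0.") out <- "0"
  paste0(if (neg) "-", out)
}

render_integer <- function(x) {
  out <- rep(NA_character_, length(x))
  idx <- which(!is.na(x))
  if (!length(idx)) return(out)
  v <- x[idx]
  integral <- is.finite(v) & v == trunc(v) & abs(v) < 1e15
  res <- character(length(v))
  res[integral] <- sprintf("%.0f", v[integral])
  if (any(!integral)) res[!integral] <- render_double(v[!integral])
  out[idx] <- res
  out
}

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  x <- xml_escape_text(x)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x <- gsub("\n", "&#10;", x, fixed = TRUE)
  gsub("\t", "&#9;", x, fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

iso_timestamp_now <- function() {
  t <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  sub("([+-][0-9]{2})([0-9]{2})$", "\\1:\\2", t)
}

new_issue_frame <- function() {
  data.frame(severity = character(0), locus = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

add_issue <- function(issues, severity, locus, message) {
  rbind(issues, data.frame(severity = severity, locus = locus,
                           message = message, stringsAsFactors = FALSE))
}
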