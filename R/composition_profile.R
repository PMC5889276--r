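# Base-composition profiling: global GC, sliding-window GC with
# extreme-region calls, and GC skew.

#' Global GC fraction
#'
#' `(#G + #C) / (#A + #C + #G + #T)`. Ambiguity letters are excluded from
#' numerator and denominator; if they exceed 0.1% of positions a warning is
#' emitted. An all-ambiguous sequence is an error.
#'
#' @param genome Genome or string.
#' @return GC fraction in [0, 1].
#' @export
global_gc <- function(genome) {
  s <- .as_seq(genome)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  gc <- sum(chars %in% c("G", "C"))
  at <- sum(chars %in% c("A", "T"))
  amb <- length(chars) - gc - at
  if (gc + at == 0L) stop("sequence contains no unambiguous bases")
  if (amb > 0.001 * length(chars))
    warning(sprintf("%d ambiguous positions (%.2f%%) excluded from GC",
                    amb, 100 * amb / length(chars)))
  gc / (gc + at)
}

#' Sliding-window GC and GC-skew profile
#'
#' Windows of `window` nt every `step` nt (the last partial window is
#' dropped). Per window: GC fraction over unambiguous bases and skew
#' `(G - C)/(G + C)` on the forward strand; windows with `G + C == 0` carry
#' skew 0 and are flagged.
#'
#' @param genome Genome or string.
#' @param window Window size in nt (default 500).
#' @param step Step in nt (default 100).
#' @return List of class `window_profile`: `window`, `step`, `start`,
#'   `center` (floor of the window midpoint), `gc`, `skew`, `skew_undefined`
#'   (logical flag per window).
#' @export
windowed_profile <- function(genome, window = 500L, step = 100L) {
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  s <- .as_seq(genome)
  n <- nchar(s)
  if (window > n) stop("window larger than sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  cg <- cumsum(c(0L, chars == "G"))
  cc <- cumsum(c(0L, chars == "C"))
  cat_ <- cumsum(c(0L, chars %in% c("A", "T")))
  starts <- seq(1L, n - window + 1L, by = step)
  ends <- starts + window - 1L
  g <- cg[ends + 1L] - cg[starts]
  c_ <- cc[ends + 1L] - cc[starts]
  at <- cat_[ends + 1L] - cat_[starts]
  denom_gc <- g + c_ + at
  gc <- ifelse(denom_gc > 0L, (g + c_) / denom_gc, NA_real_)
  undef <- (g + c_) == 0L
  skew <- ifelse(undef, 0, (g - c_) / (g + c_))
  structure(list(window = window, step = step, start = starts,
                 center = (starts + ends) %/% 2L, gc = gc, skew = skew,
                 skew_undefined = undef),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("<window_profile> %d windows (window %d, step %d); GC %.3f-%.3f\n",
              length(x$start), x$window, x$step, min(x$gc, na.rm = TRUE),
              max(x$gc, na.rm = TRUE)))
  invisible(x)
}

#' Call regions of extreme GC content from a window profile
#'
#' Maximal runs of consecutive windows at or beyond a threshold are
#' collapsed to a single region reported at the center of the run's most
#' extreme window (ties: first such window).
#'
#' @param profile A [windowed_profile()] result.
#' @param high High-GC threshold (region if gc >= high; default 0.62).
#' @param low Low-GC threshold (region if gc <= low; default 0.28).
#' @return Data frame with columns `center`, `kind` (`"high"`/`"low"`),
#'   `gc`, sorted by center.
#' @export
extreme_regions <- function(profile, high = 0.62, low = 0.28) {
  stopifnot(inherits(profile, "window_profile"), length(profile$gc) > 0L)
  call_runs <- function(flag, kind, pick) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    if (length(idx) == 0L)
      return(data.frame(center = integer(), kind = character(), gc = numeric(),
                        stringsAsFactors = FALSE))
    rows <- lapply(idx, function(i) {
      win <- starts[i]:ends[i]
      best <- win[pick(profile$gc[win])]
      data.frame(center = profile$center[best], kind = kind,
                 gc = profile$gc[best], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  hi <- call_runs(!is.na(profile$gc) & profile$gc >= high, "high", which.max)
  lo <- call_runs(!is.na(profile$gc) & profile$gc <= low, "low", which.min)
  out <- rbind(hi, lo)
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a window profile as TSV
#'
#' @param profile A [windowed_profile()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(start = profile$start, center = profile$center,
                   gc = sprintf("%.4f", profile$gc),
                   skew = sprintf("%.4f", profile$skew),
                   skew_undefined = as.integer(profile$skew_undefined))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
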