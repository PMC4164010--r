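# zcurve: cumulative Z-curve components, disparity curves, extremum location
# and rotation of a circular genome to the GC-disparity maximum.
#
# Per-base increments for (x, y, z) = (R-Y, M-K, W-S):
#   A: (+1, +1, +1)   G: (+1, -1, -1)   C: (-1, +1, -1)   T: (-1, -1, +1)
# Ambiguous IUPAC bases contribute (0, 0, 0).
# AT disparity = (x + y)/2 = cumulative #A - #T
# GC disparity = (x - y)/2 = cumulative #G - #C

#' Compute the Z-curve profile of a nucleotide sequence
#'
#' Returns the three cumulative Z-curve components and the four disparity
#' curves as length `n + 1` arrays over prefix lengths `0..n`. The `x`
#' component is the RY (purine minus pyrimidine) disparity curve, `y` the MK
#' (amino minus keto) curve; the AT and GC disparity curves are the
#' half-integer combinations `(x + y)/2` and `(x - y)/2`, i.e. the cumulative
#' excess of A over T and of G over C.
#'
#' @param sequence nucleotide string (IUPAC codes allowed; ambiguity codes
#'   contribute nothing to any component). An empty string yields the
#'   degenerate single-zero profile.
#' @return object of class `zcurve_profile`: list with `n` and numeric
#'   vectors `x`, `y`, `z`, `at`, `gc`, each of length `n + 1`.
#' @export
compute_zcurve <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(v)
  dx <- dy <- dz <- integer(n)
  a <- v == "A"; g <- v == "G"; c_ <- v == "C"; t <- v == "T"
  dx[a | g] <- 1L; dx[c_ | t] <- -1L
  dy[a | c_] <- 1L; dy[g | t] <- -1L
  dz[a | t] <- 1L; dz[g | c_] <- -1L
  x <- c(0, cumsum(dx)); y <- c(0, cumsum(dy)); z <- c(0, cumsum(dz))
  structure(list(n = n, x = x, y = y, z = z,
                 at = (x + y) / 2, gc = (x - y) / 2),
            class = "zcurve_profile")
}

#' @export
print.zcurve_profile <- function(x, ...) {
  cat(sprintf("zcurve_profile: %d bp; final at=%g gc=%g ry=%d mk=%d\n",
              x$n, x$at[x$n + 1], x$gc[x$n + 1], x$x[x$n + 1], x$y[x$n + 1]))
  invisible(x)
}

disparity_curve <- function(profile, component = c("at", "gc", "ry", "mk")) {
  component <- match.arg(component)
  switch(component, at = profile$at, gc = profile$gc,
         ry = profile$x, mk = profile$y)
}

#' Locate the extrema of a disparity curve
#'
#' Finds the positions (prefix lengths, 0-based) of the global maximum and
#' minimum of the chosen disparity curve, optionally after moving-average
#' smoothing, plus local extrema exceeding a prominence threshold. Ties are
#' broken by the smallest position. A constant curve is reported with both
#' extrema at position 0 and `flat = TRUE`.
#'
#' @param profile a `zcurve_profile` from [compute_zcurve()].
#' @param component one of `"at"`, `"gc"`, `"ry"`, `"mk"`.
#' @param smoothing_window moving-average window in bp; `NULL` (default)
#'   selects 0 (no smoothing) for sequences under 1 Mb and `n/1000` above.
#' @param prominence minimum prominence for listed local extrema, as a
#'   fraction of the curve range (default 0.1).
#' @param local also compute the local-extrema list (default TRUE; the
#'   global extrema are much cheaper on chromosome-scale curves).
#' @return list with `max_position`, `min_position` (0-based positions on
#'   the curve), `max_value`, `min_value`, `flat` (logical), and
#'   `local_extrema`, a data.frame of `position`, `value`, `kind`.
#' @export
find_extrema <- function(profile, component = c("at", "gc", "ry", "mk"),
                         smoothing_window = NULL, prominence = 0.1,
                         local = TRUE) {
  v <- disparity_curve(profile, component)
  n <- profile$n
  if (is.null(smoothing_window)) {
    smoothing_window <- if (n < 1e6) 0L else as.integer(n / 1000)
  }
  if (smoothing_window > 1L && length(v) > smoothing_window) {
    sm <- as.numeric(stats::filter(v, rep(1 / smoothing_window, smoothing_window),
                                   sides = 2))
    v <- ifelse(is.na(sm), v, sm)
  }
  rng <- range(v)
  if (rng[1] == rng[2]) {
    return(list(max_position = 0L, min_position = 0L,
                max_value = v[1], min_value = v[1], flat = TRUE,
                local_extrema = data.frame(position = integer(),
                                           value = numeric(),
                                           kind = character())))
  }
  imax <- which.max(v); imin <- which.min(v)   # which.* -> first = smallest pos
  le <- if (local) local_extrema(v, prominence * diff(rng))
        else data.frame(position = integer(), value = numeric(),
                        kind = character())
  list(max_position = imax - 1L, min_position = imin - 1L,
       max_value = v[imax], min_value = v[imin], flat = FALSE,
       local_extrema = le)
}

# local maxima/minima with a prominence cut, computed on a downsampled copy
# of the curve so cost stays bounded on chromosome-scale inputs
local_extrema <- function(v, min_prom) {
  step <- max(1L, length(v) %/% 5000L)
  idx <- seq(1L, length(v), by = step)
  w <- v[idx]
  d <- sign(diff(w))
  # collapse flat runs so plateaus count once
  keep <- d != 0
  if (!any(keep)) {
    return(data.frame(position = integer(), value = numeric(), kind = character()))
  }
  turn <- which(diff(d[keep]) != 0)
  cand_i <- which(keep)[turn] + 1L
  res <- list()
  for (ci in cand_i) {
    val <- w[ci]
    left <- w[1:ci]; right <- w[ci:length(w)]
    is_max <- (ci > 1 && w[ci - 1] < val) || (ci < length(w) && w[ci + 1] < val)
    if (is_max && val >= max(w[max(1, ci - 1)], w[min(length(w), ci + 1)])) {
      # prominence of a peak: drop to the higher of the two flanking valleys
      # bounded by the nearest higher points
      lh <- which(left > val)
      rh <- which(right > val)
      lmin <- if (length(lh)) min(left[max(lh):ci]) else min(left)
      rmin <- if (length(rh)) min(right[1:min(rh)]) else min(right)
      prom <- val - max(lmin, rmin)
      if (prom >= min_prom)
        res[[length(res) + 1L]] <- data.frame(position = (idx[ci] - 1L),
                                              value = val, kind = "max")
    } else if (!is_max) {
      lh <- which(left < val)
      rh <- which(right < val)
      lmax <- if (length(lh)) max(left[max(lh):ci]) else max(left)
      rmax <- if (length(rh)) max(right[1:min(rh)]) else max(right)
      prom <- min(lmax, rmax) - val
      if (prom >= min_prom)
        res[[length(res) + 1L]] <- data.frame(position = (idx[ci] - 1L),
                                              value = val, kind = "min")
    }
  }
  if (!length(res)) {
    return(data.frame(position = integer(), value = numeric(), kind = character()))
  }
  do.call(rbind, res)
}

#' Rotate a circular genome to the GC-disparity maximum
#'
#' Shifts the sequence and all gene coordinates so that the global maximum of
#' the GC disparity curve maps to position 0. Recomputing the profile on the
#' rotated sequence places its GC maximum at the sequence boundary. Origins
#' sit near this point on most archaeal chromosomes, so the rotated view
#' centres the replichore structure.
#'
#' @param genome a circular [annotated_genome].
#' @return the rotated [annotated_genome].
#' @export
rotate_to_gc_max <- function(genome) {
  if (!genome$circular) err_usage("rotation is undefined for a linear genome")
  n <- genome_length(genome)
  shift <- find_extrema(compute_zcurve(genome$sequence), "gc")$max_position %% n
  rotate_genome(genome, shift)
}

# rotate so that forward-strand position `shift` maps to 0
rotate_genome <- function(genome, shift) {
  n <- genome_length(genome)
  shift <- shift %% n
  if (shift == 0L) return(genome)
  seq2 <- paste0(substr(genome$sequence, shift + 1L, n),
                 substr(genome$sequence, 1L, shift))
  g <- genome$genes
  if (nrow(g)) {
    len <- g$end - g$start
    g$start <- (g$start - shift) %% n
    g$end <- g$start + len
  }
  annotated_genome(genome$accession, seq2, g, circular = genome$circular,
                   taxonomy = genome$taxonomy)
}

#' Write disparity curves as TSV
#'
#' Columns: position, x, y, z, at, gc. Positions are prefix lengths 0..n; for
#' large genomes set `step` to thin the output.
#'
#' @param profile a `zcurve_profile`.
#' @param path output path.
#' @param step report every `step`-th position (default 1).
#' @return invisibly, `path`.
#' @export
write_zcurve_tsv <- function(profile, path, step = 1L) {
  idx <- seq(1L, profile$n + 1L, by = step)
  df <- data.frame(position = idx - 1L, x = profile$x[idx], y = profile$y[idx],
                   z = profile$z[idx], at = profile$at[idx],
                   gc = profile$gc[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot the four disparity curves
#'
#' One panel per curve (AT, GC, RY, MK) with tick marks at
#' replication-related genes and arrows at predicted origin regions.
#'
#' @param genome an [annotated_genome] (roles are used if annotated).
#' @param predictions optional predictions data.frame from [predict_oric()].
#' @param file optional output file; extension selects the device (`.png` or
#'   `.svg`). `NULL` draws on the current device.
#' @return invisibly, `NULL`.
#' @export
plot_disparity_curves <- function(genome, predictions = NULL, file = NULL) {
  profile <- compute_zcurve(genome$sequence)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "png") grDevices::png(file, width = 900, height = 900)
    else if (ext == "svg") grDevices::svg(file, width = 9, height = 9)
    else err_usage("plot file must end in .png or .svg")
    on.exit(grDevices::dev.off())
  }
  comps <- c(at = "AT disparity", gc = "GC disparity",
             ry = "RY disparity", mk = "MK disparity")
  rep_genes <- genome$genes[genome$genes$role != "none", , drop = FALSE]
  op <- graphics::par(mfrow = c(4, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  step <- max(1L, profile$n %/% 20000L)
  idx <- seq(1L, profile$n + 1L, by = step)
  for (k in names(comps)) {
    v <- disparity_curve(profile, k)
    graphics::plot(idx - 1L, v[idx], type = "l", xlab = "", ylab = comps[[k]],
                   main = if (k == "at") genome$accession else "")
    if (nrow(rep_genes))
      graphics::rug(rep_genes$start, col = "red", lwd = 2)
    if (!is.null(predictions) && nrow(predictions))
      graphics::arrows(x0 = (predictions$start + predictions$end) / 2,
                       y0 = max(v) , y1 = max(v) * 0.85,
                       length = 0.08, col = "black")
  }
  invisible(NULL)
}
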