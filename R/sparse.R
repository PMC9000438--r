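#' The seven fixed QCL wavenumbers
#'
#' The sparse channel set used for cartilage work: 850 (water libration),
#' 1080 (carbohydrate C-O), 1210 (amide III), 1560 (amide II), 1620
#' (amide I), 1745 (lipid C=O) and 1800 cm^-1 (baseline estimation).
#'
#' @return Numeric vector of the seven wavenumbers, ascending, in cm^-1.
#' @export
miracle_channels <- function() {
  c(850, 1080, 1210, 1560, 1620, 1745, 1800)
}

#' Subset a broadband dataset to sparse target wavenumbers
#'
#' Emulates fixed-wavelength QCL acquisition by picking, for each target
#' wavenumber, the nearest axis channel within `tolerance` (ties broken
#' toward the lower wavenumber, for determinism). With
#' `method = "interpolate"` the rows are instead linearly interpolated at
#' the exact target wavenumbers.
#'
#' @param dataset An `ir_dataset`.
#' @param targets Target wavenumbers (cm^-1), default [miracle_channels()].
#' @param tolerance Maximum allowed |target - matched| in cm^-1; default is
#'   one axis spacing (median channel step). Ignored for
#'   `method = "interpolate"`.
#' @param method `"nearest"` (default, hardware-faithful) or
#'   `"interpolate"`.
#' @return A list with `dataset` (the sparse `ir_dataset`, same ids) and
#'   `selection`, an `ir_channel_selection` with fields `targets`,
#'   `matched`, `indices`, `tolerance`, `method`.
#' @export
select_channels <- function(dataset, targets = miracle_channels(),
                            tolerance = NULL,
                            method = c("nearest", "interpolate")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "ir_dataset"))
  targets <- sort(as.numeric(targets))
  if (length(targets) < 1L)
    ir_stop("at least one target wavenumber required", "ir_contract_error")
  axis <- dataset$axis
  if (is.null(tolerance) && method == "nearest")
    tolerance <- if (length(axis) > 1L) stats::median(diff(axis)) else 0
  # range check with `tolerance` slack so that re-selecting the nominal
  # targets from an already-subset dataset (whose end channels sit within
  # tolerance of the targets) stays legal: selection is then a projection
  slack <- if (method == "nearest") tolerance else 0
  out <- targets < min(axis) - slack | targets > max(axis) + slack
  if (any(out))
    ir_stop(sprintf("target %.6g cm-1 outside the dataset axis [%.6g, %.6g]",
                    targets[out][1L], min(axis), max(axis)), "ir_range_error")

  if (method == "interpolate") {
    m <- t(apply(dataset$matrix, 1L, function(y)
      stats::approx(axis, y, xout = targets, method = "linear",
                    ties = "ordered")$y))
    sel <- structure(list(targets = targets, matched = targets,
                          indices = rep(NA_integer_, length(targets)),
                          tolerance = NA_real_, method = method),
                     class = "ir_channel_selection")
    return(list(dataset = ir_dataset(targets, m, ids = dataset$ids),
                selection = sel))
  }

  if (!is.numeric(tolerance) || tolerance < 0)
    ir_stop("tolerance must be >= 0", "ir_contract_error")
  # nearest channel per target; which.min takes the first (= lower
  # wavenumber) index on ties because the axis is ascending
  indices <- vapply(targets, function(tg) which.min(abs(axis - tg)), 1L)
  dist <- abs(axis[indices] - targets)
  if (any(dist > tolerance))
    ir_stop(sprintf("no axis channel within %.6g cm-1 of target %.6g cm-1 (nearest is %.6g)",
                    tolerance, targets[dist > tolerance][1L],
                    axis[indices[dist > tolerance][1L]]),
            "ir_unmatched_error")
  if (anyDuplicated(indices))
    ir_stop(sprintf("targets %s map to the same axis channel %.6g cm-1",
                    paste(targets[indices == indices[duplicated(indices)][1L]],
                          collapse = ", "),
                    axis[indices[duplicated(indices)][1L]]),
            "ir_collision_error")
  sel <- structure(list(targets = targets, matched = axis[indices],
                        indices = as.integer(indices),
                        tolerance = tolerance, method = method),
                   class = "ir_channel_selection")
  list(dataset = ir_dataset(axis[indices],
                            dataset$matrix[, indices, drop = FALSE],
                            ids = dataset$ids),
       selection = sel)
}

#' @export
print.ir_channel_selection <- function(x, ...) {
  cat(sprintf("<ir_channel_selection: %d targets, method '%s'>\n",
              length(x$targets), x$method))
  for (k in seq_along(x$targets))
    cat(sprintf("  %8.4g -> %8.6g cm-1\n", x$targets[k], x$matched[k]))
  invisible(x)
}
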