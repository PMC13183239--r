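#' Construct a spectra set
#'
#' A `spectra_set` holds an aligned wavelength grid and one reflectance vector
#' per leaf.  Reflectance is stored as a fraction; values in (1, 1.2] are
#' tolerated with a warning (slight over-unity readings occur against a white
#' reference), values outside [0, 1.2] are rejected.
#'
#' @param wavelengths strictly increasing numeric vector, nm.
#' @param reflectance numeric matrix, leaves x bands.
#' @param leaf_ids unique character identifiers, one per row.
#' @return object of class `"spectra_set"` with elements `wavelengths`,
#'   `reflectance` (rownames = leaf ids), `leaf_ids`.
#' @export
spectra_set <- function(wavelengths, reflectance, leaf_ids = rownames(reflectance)) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (is.null(leaf_ids)) leaf_ids <- paste0("leaf_", seq_len(nrow(reflectance)))
  leaf_ids <- as.character(leaf_ids)
  if (anyDuplicated(wavelengths)) stop("duplicate wavelengths in grid")
  if (is.unsorted(wavelengths, strictly = TRUE)) stop("wavelengths must be strictly increasing")
  if (ncol(reflectance) != length(wavelengths)) {
    stop("reflectance column count does not match wavelength count")
  }
  if (anyDuplicated(leaf_ids)) stop("duplicate leaf ids")
  if (length(leaf_ids) != nrow(reflectance)) stop("one leaf id per spectrum required")
  if (any(!is.finite(reflectance))) stop("non-finite reflectance values")
  bad <- which(reflectance < 0 | reflectance > 1.2, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("reflectance outside [0, 1.2]: leaf '%s' at %g nm (value %g)",
                 leaf_ids[bad[1, 1]], wavelengths[bad[1, 2]],
                 reflectance[bad[1, 1], bad[1, 2]]))
  }
  over <- which(reflectance > 1, arr.ind = TRUE)
  if (nrow(over) > 0) {
    warning(sprintf("%d reflectance value(s) in (1, 1.2], e.g. leaf '%s' at %g nm",
                    nrow(over), leaf_ids[over[1, 1]], wavelengths[over[1, 2]]))
  }
  rownames(reflectance) <- leaf_ids
  colnames(reflectance) <- band_names(wavelengths)
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 leaf_ids = leaf_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d leaves x %d bands (%g-%g nm)\n",
              length(x$leaf_ids), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Band column names for a wavelength grid
#'
#' Wide-format spectra files use one column per band named `wl_<nnnn>` with a
#' zero-padded integer part (fractional grids keep their decimals).
#' @param wavelengths numeric vector, nm.
#' @export
band_names <- function(wavelengths) {
  ifelse(wavelengths == round(wavelengths),
         sprintf("wl_%04d", as.integer(round(wavelengths))),
         sprintf("wl_%s", format(wavelengths, trim = TRUE)))
}

#' Read reflectance spectra from CSV
#'
#' Two layouts are supported.  Wide: first column `leaf_id`, remaining columns
#' `wl_<nnnn>` (or bare numbers).  Long: columns `leaf_id`, `wavelength_nm`,
#' `reflectance`; every leaf must be observed on the same grid.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @return a [spectra_set()].
#' @export
read_spectra <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop(sprintf("spectra file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    if (ncol(df) < 2) stop("wide layout needs a leaf_id column plus bands")
    ids <- as.character(df[[1]])
    wl <- suppressWarnings(as.numeric(sub("^wl_0*", "", names(df)[-1])))
    if (anyNA(wl)) stop("unparseable wavelength column names in wide spectra file")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric reflectance values in spectra file")
    o <- order(wl)
    spectra_set(wl[o], m[, o, drop = FALSE], ids)
  } else {
    need <- c("leaf_id", "wavelength_nm", "reflectance")
    if (!all(need %in% names(df))) {
      stop("long layout needs columns leaf_id, wavelength_nm, reflectance")
    }
    if (!is.numeric(df$reflectance)) stop("non-numeric reflectance values")
    if (!is.numeric(df$wavelength_nm)) stop("non-numeric wavelengths")
    if (anyDuplicated(df[c("leaf_id", "wavelength_nm")])) {
      stop("duplicate (leaf_id, wavelength) pairs in long spectra file")
    }
    ids <- unique(df$leaf_id)
    wl <- sort(unique(df$wavelength_nm))
    counts <- table(df$leaf_id)
    if (length(unique(counts)) != 1 || unique(counts) != length(wl)) {
      stop("inconsistent wavelength grids across leaves in long spectra file")
    }
    m <- matrix(NA_real_, length(ids), length(wl),
                dimnames = list(ids, NULL))
    m[cbind(match(df$leaf_id, ids), match(df$wavelength_nm, wl))] <- df$reflectance
    if (anyNA(m)) stop("inconsistent wavelength grids across leaves in long spectra file")
    spectra_set(wl, m, ids)
  }
}

#' Write reflectance spectra to CSV
#'
#' @param s a [spectra_set()].
#' @param path output CSV path.
#' @param layout `"wide"` or `"long"` (see [read_spectra()]).
#' @export
write_spectra <- function(s, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(s, "spectra_set"))
  if (layout == "wide") {
    df <- data.frame(leaf_id = s$leaf_ids, s$reflectance,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    df <- data.frame(
      leaf_id = rep(s$leaf_ids, each = length(s$wavelengths)),
      wavelength_nm = rep(s$wavelengths, times = length(s$leaf_ids)),
      reflectance = as.vector(t(s$reflectance)),
      stringsAsFactors = FALSE
    )
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Trim and resample spectra to a uniform grid
#'
#' Restricts the spectral window and linearly interpolates every leaf onto a
#' regular grid.  The defaults (400-2400 nm at 1 nm) give the 2001-band grid
#' used throughout the trait-modelling protocol; edge regions of full-range
#' instruments (below 400, above 2400 nm) are noisy and dropped.
#'
#' @param s a [spectra_set()].
#' @param lower,upper window bounds, nm (inclusive); input must cover them.
#' @param step grid step, nm.
#' @return a [spectra_set()] on the new grid.  Idempotent when the input is
#'   already on the requested grid.
#' @export
trim_and_resample <- function(s, lower = 400, upper = 2400, step = 1) {
  stopifnot(inherits(s, "spectra_set"), lower < upper, step > 0)
  if (min(s$wavelengths) > lower || max(s$wavelengths) < upper) {
    stop(sprintf("input grid %g-%g nm does not cover the requested %g-%g nm window",
                 min(s$wavelengths), max(s$wavelengths), lower, upper))
  }
  grid <- seq(lower, upper, by = step)
  if (length(s$wavelengths) == length(grid) &&
      all(abs(s$wavelengths - grid) < 1e-9)) {
    return(s)
  }
  m <- t(apply(s$reflectance, 1, function(r) {
    stats::approx(s$wavelengths, r, xout = grid, method = "linear")$y
  }))
  spectra_set(grid, m, s$leaf_ids)
}

#' Per-band reflectance quantiles across leaves
#'
#' Summarizes a spectra set as quantile curves, the standard way to display a
#' population of leaf spectra with its envelope.  Quantiles use the
#' linear-interpolation (type 7) convention.
#'
#' @param s a [spectra_set()] with at least one leaf.
#' @param probs probabilities in [0, 1].
#' @return data.frame with `wavelength_nm` and one `q<prob>` column per prob.
#' @export
quantile_summary <- function(s, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(s, "spectra_set"))
  if (length(s$leaf_ids) < 1) stop("empty spectra set")
  q <- apply(s$reflectance, 2, stats::quantile, probs = probs, type = 7,
             names = FALSE)
  q <- matrix(q, nrow = length(probs))
  out <- data.frame(wavelength_nm = s$wavelengths, t(q))
  names(out)[-1] <- paste0("q", probs)
  out
}

# Named spectral windows (nm).  Red edge deliberately overlaps VIS, so region
# queries return a set of labels rather than a single one.
.spectral_regions <- data.frame(
  name  = c("VIS", "RED_EDGE", "NIR", "SWIR1", "SWIR2"),
  lower = c(380, 680, 780, 1550, 2000),
  upper = c(780, 750, 1400, 1750, 2300),
  stringsAsFactors = FALSE
)

#' Spectral region definitions
#'
#' The conventional windows for leaf optics: VIS 380-780 nm, red edge
#' 680-750 nm (a sub-window of VIS, reported separately because of its
#' diagnostic value), NIR 780-1400 nm, SWIR1 1550-1750 nm and SWIR2
#' 2000-2300 nm.  Bounds are inclusive; gaps between windows are unlabelled.
#' @return data.frame with columns `name`, `lower`, `upper`.
#' @export
spectral_regions <- function() .spectral_regions

#' Region membership of a wavelength
#'
#' @param wavelength numeric scalar, nm (within 350-2500).
#' @return character vector of region names containing the wavelength
#'   (possibly several, e.g. 700 nm is both VIS and RED_EDGE; possibly none).
#' @export
region_of <- function(wavelength) {
  stopifnot(length(wavelength) == 1, is.finite(wavelength))
  if (wavelength < 350 || wavelength > 2500) {
    stop("wavelength outside the supported 350-2500 nm range")
  }
  r <- .spectral_regions
  r$name[wavelength >= r$lower & wavelength <= r$upper]
}
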