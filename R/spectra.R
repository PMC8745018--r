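# Centroided MS/MS peak lists: construction, MGF IO, accumulation of
# replicate spectra, and matching of peaks to a theoretical fragment ladder.

#' Construct a centroided spectrum
#'
#' @param mz,intensity Numeric vectors of equal length; peaks are sorted by
#'   ascending m/z. Intensities must be non-negative and finite.
#' @param precursor_mz Precursor m/z (Da).
#' @param sample_id,replicate Identity of the acquisition.
#' @param metadata Optional named list carried through unchanged.
#' @return An object of class `ab_spectrum`.
#' @export
new_spectrum <- function(mz, intensity, precursor_mz,
                         sample_id = "sample", replicate = 1L,
                         metadata = list()) {
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ")
  if (length(mz) < 1L) stop("a spectrum needs at least one peak")
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite peak values")
  if (any(mz <= 0)) stop("m/z values must be positive")
  if (any(intensity < 0)) stop("negative intensities")
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (any(diff(mz) <= 0)) {
    # merge exact duplicates rather than reject them
    key <- cumsum(c(TRUE, diff(mz) > 0))
    intensity <- as.numeric(tapply(intensity, key, sum))
    mz <- as.numeric(tapply(mz, key, function(x) x[1]))
  }
  structure(list(sample_id = as.character(sample_id),
                 replicate = as.integer(replicate),
                 precursor_mz = as.numeric(precursor_mz),
                 peaks = data.frame(mz = mz, intensity = intensity),
                 metadata = metadata),
            class = "ab_spectrum")
}

#' @export
print.ab_spectrum <- function(x, ...) {
  cat(sprintf("ab_spectrum %s:%d  precursor %.4f  %d peaks\n",
              x$sample_id, x$replicate, x$precursor_mz, nrow(x$peaks)))
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' Parses the plain BEGIN IONS/END IONS dialect with PEPMASS and TITLE lines.
#' A TITLE of the form `sample:replicate` is split into the spectrum's
#' `sample_id` and `replicate`; any other title is stored verbatim as the
#' sample id with replicates numbered in file order.
#'
#' @param path Path to an MGF file.
#' @return A list of [new_spectrum()] objects (empty, with a warning, for an
#'   empty file).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L; n <- length(lines); block_no <- 0L
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      block_no <- block_no + 1L
      begin_line <- i
      title <- NULL; pepmass <- NULL
      mzs <- numeric(0); ints <- numeric(0)
      i <- i + 1L
      repeat {
        if (i > n)
          stop("unterminated MGF block starting at line ", begin_line)
        line <- trimws(lines[i])
        if (line == "END IONS") break
        if (grepl("^TITLE=", line)) {
          title <- sub("^TITLE=", "", line)
        } else if (grepl("^PEPMASS=", line)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line), "\\s+")[[1]][1])
        } else if (grepl("^[A-Z]+=", line) || line == "") {
          # other headers ignored
        } else {
          fields <- strsplit(line, "[\t ]+")[[1]]
          if (length(fields) < 2L || anyNA(suppressWarnings(as.numeric(fields[1:2]))))
            stop("malformed peak line ", i, ": '", lines[i], "'")
          mzs <- c(mzs, as.numeric(fields[1]))
          ints <- c(ints, as.numeric(fields[2]))
        }
        i <- i + 1L
      }
      if (is.null(pepmass) || is.na(pepmass))
        stop("MGF block ", block_no, " (line ", begin_line, ") lacks PEPMASS")
      if (length(mzs) == 0L)
        stop("MGF block ", block_no, " (line ", begin_line, ") has no peaks")
      sample_id <- if (is.null(title)) paste0("block", block_no) else title
      replicate <- block_no
      if (!is.null(title) && grepl("^[^:]+:[0-9]+$", title)) {
        parts <- strsplit(title, ":")[[1]]
        sample_id <- parts[1]
        replicate <- as.integer(parts[2])
      }
      spectra[[length(spectra) + 1L]] <-
        new_spectrum(mzs, ints, pepmass, sample_id, replicate)
    } else if (nzchar(line)) {
      # stray content outside blocks is tolerated (comments, charge lines)
    }
    i <- i + 1L
  }
  if (length(spectra) == 0L) warning("no spectra found in ", path)
  spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]; TITLE is written as `sample_id:replicate`.
#'
#' @param spectra A list of `ab_spectrum` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ab_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=%s:%d", s$sample_id, s$replicate),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Accumulate replicate MS/MS spectra
#'
#' Sums centroided replicates of the same precursor: peaks from all spectra
#' are pooled, sorted, and clustered greedily (a gap larger than
#' `bin_tolerance_da` starts a new cluster); each cluster becomes one peak at
#' the intensity-weighted mean m/z with the summed intensity. Total intensity
#' is conserved exactly and the result does not depend on input order.
#'
#' @param spectra List of `ab_spectrum` sharing a precursor.
#' @param bin_tolerance_da Clustering gap (Da); default 0.02.
#' @return One accumulated `ab_spectrum` (replicate 0).
#' @export
accumulate <- function(spectra, bin_tolerance_da = 0.02) {
  if (inherits(spectra, "ab_spectrum")) spectra <- list(spectra)
  if (length(spectra) < 1L) stop("need at least one spectrum")
  prec <- vapply(spectra, function(s) s$precursor_mz, 0)
  if (max(prec) - min(prec) > bin_tolerance_da)
    stop("mixed precursors: range ", signif(max(prec) - min(prec), 3),
         " Da exceeds bin tolerance")
  mz <- unlist(lapply(spectra, function(s) s$peaks$mz))
  intensity <- unlist(lapply(spectra, function(s) s$peaks$intensity))
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  cluster <- cumsum(c(TRUE, diff(mz) > bin_tolerance_da))
  out_int <- as.numeric(tapply(intensity, cluster, sum))
  out_mz <- as.numeric(tapply(seq_along(mz), cluster, function(i) {
    w <- intensity[i]
    if (sum(w) == 0) mean(mz[i]) else sum(mz[i] * w) / sum(w)
  }))
  new_spectrum(out_mz, out_int, mean(prec),
               sample_id = spectra[[1]]$sample_id, replicate = 0L)
}

#' Match spectrum peaks to a theoretical fragment ladder
#'
#' For every theoretical ion the nearest observed peak within `tolerance_da`
#' is assigned; each peak is used at most once. Conflicts are resolved by
#' smallest mass error, then higher peak intensity, then lower m/z.
#'
#' @param spectrum An `ab_spectrum`.
#' @param ladder Data frame from [theoretical_ladder()] (columns `label`,
#'   `mz`).
#' @param tolerance_da Match window (Da); default 0.05, the standard fragment
#'   tolerance for this instrument class.
#' @return An object of class `ab_matchset`: a data.frame with one row per
#'   theoretical ion (`label`, `theo_mz`, `matched`, `peak_mz`, `intensity`)
#'   plus attributes `tolerance_da` and `spectrum_id`.
#' @export
match_fragments <- function(spectrum, ladder, tolerance_da = 0.05) {
  if (!inherits(spectrum, "ab_spectrum")) stop("spectrum must be an ab_spectrum")
  if (!is.data.frame(ladder) || nrow(ladder) == 0L)
    stop("ladder must be a non-empty data.frame")
  if (tolerance_da <= 0) stop("tolerance_da must be positive")
  peaks <- spectrum$peaks
  n_ion <- nrow(ladder)
  # candidate (ion, peak) pairs within tolerance; peaks$mz is sorted, so the
  # candidates of ion i are a contiguous index range
  lo <- findInterval(ladder$mz - tolerance_da, peaks$mz) + 1L
  hi <- findInterval(ladder$mz + tolerance_da, peaks$mz)
  counts <- pmax(hi - lo + 1L, 0L)
  cand_ion <- rep.int(seq_len(n_ion), counts)
  cand_peak <- unlist(lapply(which(counts > 0L),
                             function(i) lo[i]:hi[i]), use.names = FALSE)
  assigned_peak <- rep(NA_integer_, n_ion)
  if (length(cand_peak)) {
    err <- abs(peaks$mz[cand_peak] - ladder$mz[cand_ion])
    ord <- order(err, -peaks$intensity[cand_peak], peaks$mz[cand_peak])
    used_peak <- logical(nrow(peaks))
    for (k in ord) {
      i <- cand_ion[k]; j <- cand_peak[k]
      if (is.na(assigned_peak[i]) && !used_peak[j]) {
        assigned_peak[i] <- j
        used_peak[j] <- TRUE
      }
    }
  }
  out <- data.frame(
    label = ladder$label,
    theo_mz = ladder$mz,
    matched = !is.na(assigned_peak),
    peak_mz = ifelse(is.na(assigned_peak), NA_real_, peaks$mz[assigned_peak]),
    intensity = ifelse(is.na(assigned_peak), NA_real_,
                       peaks$intensity[assigned_peak]),
    stringsAsFactors = FALSE
  )
  attr(out, "tolerance_da") <- tolerance_da
  attr(out, "spectrum_id") <- paste0(spectrum$sample_id, ":", spectrum$replicate)
  class(out) <- c("ab_matchset", "data.frame")
  out
}
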