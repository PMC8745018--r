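# Sequence constants, modification definitions and fragment-mass arithmetic
# for the Abeta region of APP, in 1-based Abeta numbering. Position -1 is the
# Met immediately preceding D1 (the "M(-1)" proteoform); there is no position 0.

# Monoisotopic residue masses (Da), standard 20-letter alphabet.
AA_MONO <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

PROTON_MASS <- 1.007276467
WATER_MASS  <- 18.010565

# Human Abeta 1-43 and the murine ortholog. The two differ only at positions
# 5, 10 and 13 (R5G, Y10F, H13R); 17-43 is identical between species.
.AB_SEQ <- list(
  human  = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIAT",
  murine = "DAEFGHDSGFEVRHQKLVFFAEDVGSNKGAIIGLMVGGVVIAT"
)
.AB_MET_MINUS1 <- "M"  # residue at Abeta position -1 (both species)

#' Modification definitions
#'
#' Variable modifications considered on Abeta peptides, with Unimod
#' monoisotopic mass deltas. `iso_asp` (Asp -> isoAsp isomerization) is
#' mass-silent: its delta is exactly 0, which is why it must be quantified
#' through fragment intensity ratios rather than a mass shift.
#'
#' @format A named list; each element has `name`, `targets` (one-letter
#'   residue codes the modification may sit on), `mono_delta` (Da) and
#'   `positional_rule` (`"any"` or `"peptide_nterm_only"`).
#' @export
AB_MODIFICATIONS <- list(
  deamidation = list(name = "deamidation", targets = c("N", "Q"),
                     mono_delta = 0.984016, positional_rule = "any"),
  oxidation = list(name = "oxidation", targets = "M",
                   mono_delta = 15.994915, positional_rule = "any"),
  phosphorylation = list(name = "phosphorylation", targets = c("S", "T", "Y"),
                         mono_delta = 79.966331, positional_rule = "any"),
  pyroglutamate_E = list(name = "pyroglutamate_E", targets = "E",
                         mono_delta = -18.010565,
                         positional_rule = "peptide_nterm_only"),
  pyroglutamate_Q = list(name = "pyroglutamate_Q", targets = "Q",
                         mono_delta = -17.026549,
                         positional_rule = "peptide_nterm_only"),
  iso_asp = list(name = "iso_asp", targets = "D",
                 mono_delta = 0, positional_rule = "any")
)

# map an Abeta coordinate (-1, 1..43) to an index into the M-prefixed string
.ab_coord_index <- function(pos) {
  if (any(pos == 0)) stop("Abeta coordinate 0 does not exist (use -1 or 1..43)")
  ifelse(pos == -1L, 1L, pos + 1L)
}

#' Retrieve an Abeta sub-sequence
#'
#' Returns the residues of the Abeta region between two positions in 1-based
#' Abeta numbering. Positions 1-16 are species-specific (human and murine
#' differ at positions 5, 10 and 13); positions 17-43 are shared. Position -1
#' denotes the Met preceding D1.
#'
#' @param species `"human"` or `"murine"`.
#' @param start,end Abeta coordinates, `-1 <= start <= end <= 43`, `start != 0`.
#' @return An object of class `ab_sequence`: a list with `residues`
#'   (one-letter string), `species` and `start_position`.
#' @examples
#' get_sequence("human", 1, 16)$residues   # "DAEFRHDSGYEVHHQK"
#' get_sequence("murine", 1, 16)$residues  # "DAEFGHDSGFEVRHQK"
#' @export
get_sequence <- function(species = c("human", "murine"), start, end) {
  species <- match.arg(species)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing integers")
  if (start == 0 || end == 0)
    stop("Abeta coordinate 0 does not exist (allowed: -1, 1..43)")
  if (start < -1) stop("start below lower bound -1: ", start)
  if (end > 43) stop("end above upper bound 43: ", end)
  if (start > end) stop("empty range: start (", start, ") > end (", end, ")")
  full <- paste0(.AB_MET_MINUS1, .AB_SEQ[[species]])
  res <- substr(full, .ab_coord_index(start), .ab_coord_index(end))
  structure(list(residues = res, species = species, start_position = as.integer(start)),
            class = "ab_sequence")
}

#' @export
print.ab_sequence <- function(x, ...) {
  cat(sprintf("Abeta %s(%d-%d): %s\n", x$species, x$start_position,
              x$start_position + nchar(x$residues) - 1L -
                (x$start_position == -1L), x$residues))
  invisible(x)
}

.as_ab_sequence <- function(seq) {
  if (inherits(seq, "ab_sequence")) return(seq)
  if (is.character(seq) && length(seq) == 1L)
    return(structure(list(residues = seq, species = NA_character_,
                          start_position = 1L), class = "ab_sequence"))
  stop("expected an ab_sequence or a single residue string")
}

# residue position (Abeta coords) of the i-th residue of the peptide
.peptide_positions <- function(seq) {
  n <- nchar(seq$residues)
  start <- seq$start_position
  if (is.na(start)) start <- 1L
  pos <- start + seq_len(n) - 1L
  if (start == -1L) pos[pos >= 0L] <- pos[pos >= 0L] + 1L  # skip nonexistent 0
  pos
}

# validate a mods spec and return per-peptide-residue mass deltas.
# mods: data.frame(position, name) or list of list(position=, name=);
# positions are in the same coordinates as the peptide (Abeta numbering when
# the sequence came from get_sequence).
.mod_deltas <- function(seq, mods) {
  n <- nchar(seq$residues)
  deltas <- numeric(n)
  mods <- .normalize_mods(mods)
  if (nrow(mods) == 0L) return(deltas)
  pos_map <- .peptide_positions(seq)
  residues <- strsplit(seq$residues, "")[[1]]
  for (i in seq_len(nrow(mods))) {
    name <- mods$name[i]
    spec <- AB_MODIFICATIONS[[name]]
    if (is.null(spec)) stop("unknown modification: ", name)
    idx <- match(mods$position[i], pos_map)
    if (is.na(idx))
      stop("modification position ", mods$position[i], " outside peptide")
    if (!(residues[idx] %in% spec$targets))
      stop(sprintf("modification '%s' not allowed on residue %s at position %d",
                   name, residues[idx], mods$position[i]))
    if (spec$positional_rule == "peptide_nterm_only" && idx != 1L)
      stop(sprintf("'%s' is restricted to the peptide N-terminus", name))
    deltas[idx] <- deltas[idx] + spec$mono_delta
  }
  deltas
}

.normalize_mods <- function(mods) {
  if (is.null(mods) || (is.list(mods) && length(mods) == 0L))
    return(data.frame(position = integer(), name = character()))
  if (is.data.frame(mods))
    return(data.frame(position = as.integer(mods$position),
                      name = as.character(mods$name)))
  data.frame(position = vapply(mods, function(m) as.integer(m$position), 1L),
             name = vapply(mods, function(m) as.character(m$name), ""))
}

#' Monoisotopic m/z of a b or y fragment ion
#'
#' Standard CID fragment arithmetic for singly and multiply protonated ions:
#' `b_n` is the sum of the first `n` residue masses plus `n_charge` protons;
#' `y_n` adds water for the C-terminal fragment. Modification deltas are added
#' for every modified residue the fragment covers.
#'
#' @param seq An `ab_sequence` (or plain residue string, taken as starting at
#'   position 1).
#' @param series `"b"` or `"y"`.
#' @param index Fragment index, `1 <= index < length(seq)`.
#' @param mods Modifications as `data.frame(position, name)` (positions in the
#'   peptide's own coordinate system) or a list of `list(position=, name=)`.
#' @param charge Positive integer charge state (MALDI spectra are singly
#'   charged; the default).
#' @return The fragment m/z in Da.
#' @examples
#' fragment_mz(get_sequence("human", 1, 16), "b", 6)   # ~756.342
#' fragment_mz(get_sequence("human", 1, 16), "y", 10)  # ~1199.544
#' @export
fragment_mz <- function(seq, series = c("b", "y"), index, mods = list(),
                        charge = 1L) {
  series <- match.arg(series)
  seq <- .as_ab_sequence(seq)
  L <- nchar(seq$residues)
  if (index < 1L || index >= L)
    stop("fragment index must satisfy 1 <= index < peptide length (", L, ")")
  if (charge < 1L) stop("charge must be a positive integer")
  residues <- strsplit(seq$residues, "")[[1]]
  bad <- setdiff(residues, names(AA_MONO))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  deltas <- .mod_deltas(seq, mods)
  masses <- AA_MONO[residues] + deltas
  covered <- if (series == "b") seq_len(index) else (L - index + 1L):L
  neutral <- sum(masses[covered]) + if (series == "y") WATER_MASS else 0
  (neutral + charge * PROTON_MASS) / charge
}

#' Monoisotopic MH+ of a peptide
#'
#' @inheritParams fragment_mz
#' @return The singly protonated monoisotopic mass (Da).
#' @export
peptide_mh <- function(seq, mods = list()) {
  seq <- .as_ab_sequence(seq)
  residues <- strsplit(seq$residues, "")[[1]]
  bad <- setdiff(residues, names(AA_MONO))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  sum(AA_MONO[residues] + .mod_deltas(seq, mods)) + WATER_MASS + PROTON_MASS
}

#' Full singly-charged b/y fragment ladder
#'
#' All `b_1..b_{L-1}` and `y_1..y_{L-1}` singly charged ions of a peptide,
#' sorted by m/z. Every complementary pair satisfies
#' `mz(b_n) + mz(y_{L-n}) = MH+ + proton`.
#'
#' @inheritParams fragment_mz
#' @return A data.frame with columns `label` (e.g. `"b6"`), `series`, `index`,
#'   `mz`.
#' @export
theoretical_ladder <- function(seq, mods = list()) {
  seq <- .as_ab_sequence(seq)
  L <- nchar(seq$residues)
  if (L < 2L) stop("peptide too short to fragment")
  idx <- seq_len(L - 1L)
  out <- data.frame(
    label = c(paste0("b", idx), paste0("y", idx)),
    series = rep(c("b", "y"), each = L - 1L),
    index = c(idx, idx),
    mz = c(vapply(idx, function(i) fragment_mz(seq, "b", i, mods), 0),
           vapply(idx, function(i) fragment_mz(seq, "y", i, mods), 0)),
    stringsAsFactors = FALSE
  )
  out[order(out$mz), , drop = FALSE]
}

#' Classify a peptide as human, murine, shared or unknown
#'
#' Matches the residue string against the species-specific Abeta 1-16 region
#' and the shared 17-43 region (including the M(-1)-extended forms). Peptides
#' found only in the shared C-terminal region cannot be attributed to a
#' species and are labelled `"shared"`.
#'
#' @param residues Non-empty one-letter residue string.
#' @return One of `"human"`, `"murine"`, `"shared"`, `"unknown"`.
#' @export
classify_peptide <- function(residues) {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string")
  full_h <- paste0(.AB_MET_MINUS1, .AB_SEQ$human)
  full_m <- paste0(.AB_MET_MINUS1, .AB_SEQ$murine)
  in_h <- grepl(residues, full_h, fixed = TRUE)
  in_m <- grepl(residues, full_m, fixed = TRUE)
  if (in_h && in_m) {
    # both: lies entirely in a region where the species agree
    shared_region <- substr(full_h, .ab_coord_index(17L), .ab_coord_index(43L))
    if (grepl(residues, shared_region, fixed = TRUE)) return("shared")
    # short N-terminal fragments identical between species (e.g. "DAEF")
    return("shared")
  }
  if (in_h) return("human")
  if (in_m) return("murine")
  "unknown"
}
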