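#' Peptidoforms
#'
#' A peptidoform is a peptide sequence plus the variable modifications common
#' to endogenous peptidomics: C-terminal amidation, oxidation of methionine,
#' and N-terminal pyro-glutamate formation from Gln or Glu.
#'
#' @param sequence Amino-acid string (canonical 20-letter alphabet; `X`/`U`
#'   are tolerated in databases but not in mass computation).
#' @param amidated C-terminal amidation flag.
#' @param oxidized Integer positions of oxidised residues (must be `M`).
#' @param pyro_glu Pyro-glutamate at position 1 (residue must be `Q` or `E`).
#' @return A `peptidoform` object.
#' @export
peptidoform <- function(sequence, amidated = FALSE, oxidized = integer(),
                        pyro_glu = FALSE) {
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  if (length(oxidized)) {
    if (any(oxidized < 1 | oxidized > length(res)) ||
        any(res[oxidized] != "M")) {
      abort("oxidized positions must point at M residues")
    }
  }
  if (pyro_glu && !(res[1] %in% c("Q", "E"))) {
    abort("pyro_glu requires Q or E at position 1")
  }
  structure(list(sequence = sequence, amidated = isTRUE(amidated),
                 oxidized = sort(unique(as.integer(oxidized))),
                 pyro_glu = isTRUE(pyro_glu)),
            class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  mods <- format_mods(x)
  cat(sprintf("<peptidoform> %s%s\n", x$sequence,
              if (nzchar(mods)) paste0(" [", mods, "]") else ""))
  invisible(x)
}

#' Serialise / parse the modification string of the PSM table dialect
#'
#' Modifications are written as a semicolon-separated list of `pos:name`
#' entries, e.g. `"1:pyro_glu;4:oxidation;9:amidation"`; amidation is
#' recorded at the C-terminal position, pyro-glu at position 1.
#'
#' @param p A `peptidoform`.
#' @return For `format_mods`, a single string (empty when unmodified).
#' @export
format_mods <- function(p) {
  n <- nchar(p$sequence)
  parts <- character()
  if (p$pyro_glu) parts <- c(parts, "1:pyro_glu")
  if (length(p$oxidized)) parts <- c(parts, paste0(p$oxidized, ":oxidation"))
  if (p$amidated) parts <- c(parts, paste0(n, ":amidation"))
  paste(parts, collapse = ";")
}

#' @rdname format_mods
#' @param sequence Peptide sequence the mods apply to.
#' @param mods Modification string in the dialect above (`NA` or `""` means
#'   unmodified).
#' @export
parse_mods <- function(sequence, mods) {
  if (is.na(mods) || !nzchar(mods)) return(peptidoform(sequence))
  entries <- strsplit(mods, ";", fixed = TRUE)[[1]]
  pos <- as.integer(sub(":.*$", "", entries))
  name <- sub("^[0-9]+:", "", entries)
  if (any(!name %in% c("pyro_glu", "oxidation", "amidation"))) {
    abort(sprintf("unknown modification name in '%s'", mods))
  }
  peptidoform(sequence,
              amidated = "amidation" %in% name,
              oxidized = pos[name == "oxidation"],
              pyro_glu = "pyro_glu" %in% name)
}

# Per-residue mass deltas of a peptidoform's modifications (length = peptide
# length); amidation is attributed to the last residue, pyro-glu to the first.
mod_deltas <- function(p) {
  res <- strsplit(p$sequence, "")[[1]]
  d <- numeric(length(res))
  d[p$oxidized] <- d[p$oxidized] + MOD_OXIDATION
  if (p$pyro_glu) {
    d[1] <- d[1] + if (res[1] == "Q") MOD_PYROGLU_Q else MOD_PYROGLU_E
  }
  if (p$amidated) d[length(res)] <- d[length(res)] + MOD_AMIDATION
  d
}

residue_masses <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  m <- AA_MONO_MASS[res]
  if (anyNA(m)) {
    abort(sprintf("unsupported residue(s) in '%s': %s", sequence,
                  paste(unique(res[is.na(m)]), collapse = ", ")))
  }
  unname(m)
}

#' Monoisotopic mass of a peptidoform
#'
#' Sum of residue monoisotopic masses plus water plus modification deltas.
#'
#' @param p A `peptidoform` (or plain sequence string, treated unmodified).
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(p) {
  if (is.character(p)) p <- peptidoform(p)
  sum(residue_masses(p$sequence)) + WATER_MASS + sum(mod_deltas(p))
}

#' Theoretical b/y fragment m/z values
#'
#' Singly- and multiply-protonated b and y ions for fragment lengths 1..n-1.
#' C-terminal amidation shifts only the y series, pyro-glu only the b series,
#' oxidation follows its residue. Fragment charges up to `max_frag_charge`
#' are generated (common practice: 2 for precursors of charge >= 2, else 1).
#'
#' @param p A `peptidoform` (length >= 2).
#' @param max_frag_charge Highest fragment charge to generate.
#' @return A tibble `ion` (`"b"`/`"y"`), `idx` (fragment length), `charge`,
#'   `mz`, ordered b then y, ascending index within series, charge-major.
#' @export
fragment_mz <- function(p, max_frag_charge = 1L) {
  if (is.character(p)) p <- peptidoform(p)
  n <- nchar(p$sequence)
  if (n < 2) abort("fragmentation requires length >= 2")
  m <- residue_masses(p$sequence) + mod_deltas(p)
  b_neutral <- cumsum(m)[seq_len(n - 1)]
  y_neutral <- cumsum(rev(m))[seq_len(n - 1)] + WATER_MASS
  out <- purrr::map_dfr(seq_len(max_frag_charge), function(z) {
    bind_rows(
      tibble(ion = "b", idx = seq_len(n - 1), charge = z,
             mz = (b_neutral + z * PROTON_MASS) / z),
      tibble(ion = "y", idx = seq_len(n - 1), charge = z,
             mz = (y_neutral + z * PROTON_MASS) / z)
    )
  })
  arrange(out, .data$charge, dplyr::desc(.data$ion == "b"), .data$idx)
}

#' Match theoretical fragment m/z values to observed peaks
#'
#' For each theoretical m/z the intensity of the nearest observed peak within
#' `tol` is returned (0 when none); equidistant ties go to the higher
#' intensity; one observed peak may serve several theoretical ions.
#'
#' @param peaks A tibble/data frame of `mz`, `intensity`, sorted by `mz`.
#' @param theo_mz Numeric vector of theoretical m/z values.
#' @param tol Symmetric tolerance in Da (default 0.02, the typical fragment
#'   mass error used for TOF feature extraction).
#' @return Numeric vector of matched intensities, one per theoretical m/z.
#' @export
match_peaks <- function(peaks, theo_mz, tol = 0.02) {
  if (tol < 0) abort("tolerance must be non-negative")
  if (is.list(peaks) && !is.data.frame(peaks)) peaks <- as_tibble(peaks)
  mz <- peaks$mz; int <- peaks$intensity
  if (length(mz) == 0L) return(numeric(length(theo_mz)))
  if (is.unsorted(mz)) abort("peaks must be sorted by mz")
  lo <- findInterval(theo_mz, mz)
  hi <- pmin(lo + 1L, length(mz))
  lo <- pmax(lo, 1L)
  d_lo <- abs(theo_mz - mz[lo])
  d_hi <- abs(theo_mz - mz[hi])
  pick <- ifelse(d_lo < d_hi, lo,
          ifelse(d_hi < d_lo, hi,
                 ifelse(int[lo] >= int[hi], lo, hi)))
  d <- abs(theo_mz - mz[pick])
  ifelse(d <= tol, int[pick], 0)
}

#' Read an MGF (Mascot generic format) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks; `TITLE` becomes the spectrum id,
#' `PEPMASS` the precursor m/z, `CHARGE` (e.g. `"2+"`) the precursor charge,
#' `RTINSECONDS` the retention time. Unknown keys are preserved so that a
#' write/read round trip is lossless. An unterminated block raises an error
#' with the line number where it begins.
#'
#' @param path Path to an MGF file.
#' @return A tibble with one row per spectrum: `spectrum_id`, `precursor_mz`,
#'   `precursor_charge`, `rt`, `peaks` (list column of `mz`/`intensity`
#'   tibbles) and `extra` (list column of named character vectors).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(trimws(lines) == "BEGIN IONS")
  ends <- which(trimws(lines) == "END IONS")
  if (length(begins) != length(ends) ||
      (length(begins) && any(ends < begins))) {
    bad <- if (length(begins)) begins[length(ends) + 1L] else 1L
    abort(sprintf("unterminated MGF block starting at line %d", bad))
  }
  purrr::map2_dfr(begins, ends, function(b, e) {
    body <- trimws(lines[(b + 1L):(e - 1L)])
    body <- body[nzchar(body)]
    has_key <- grepl("=", body, fixed = TRUE)
    kv <- body[has_key]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    peak_lines <- body[!has_key]
    pk <- if (length(peak_lines)) {
      mat <- do.call(rbind, strsplit(peak_lines, "[ \t]+"))
      tibble(mz = as.numeric(mat[, 1]), intensity = as.numeric(mat[, 2]))
    } else tibble(mz = numeric(), intensity = numeric())
    charge <- NA_integer_
    if ("CHARGE" %in% keys) {
      cv <- vals[match("CHARGE", keys)]
      sign <- if (grepl("-", cv, fixed = TRUE)) -1L else 1L
      charge <- sign * as.integer(gsub("[^0-9]", "", cv))
    }
    known <- c("TITLE", "PEPMASS", "CHARGE", "RTINSECONDS")
    extra <- setNames(vals[!keys %in% known], keys[!keys %in% known])
    tibble(
      spectrum_id = if ("TITLE" %in% keys) vals[match("TITLE", keys)]
                    else NA_character_,
      precursor_mz = if ("PEPMASS" %in% keys)
        as.numeric(strsplit(vals[match("PEPMASS", keys)], "[ \t]+")[[1]][1])
        else NA_real_,
      precursor_charge = charge,
      rt = if ("RTINSECONDS" %in% keys)
        as.numeric(vals[match("RTINSECONDS", keys)]) else NA_real_,
      peaks = list(pk),
      extra = list(extra)
    )
  })
}

#' Write spectra as MGF
#'
#' @param spectra A tibble as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    writeLines("BEGIN IONS", con)
    if (!is.na(spectra$spectrum_id[i])) {
      writeLines(paste0("TITLE=", spectra$spectrum_id[i]), con)
    }
    if (!is.na(spectra$precursor_mz[i])) {
      writeLines(sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]), con)
    }
    if (!is.na(spectra$precursor_charge[i])) {
      z <- spectra$precursor_charge[i]
      writeLines(sprintf("CHARGE=%d%s", abs(z), if (z < 0) "-" else "+"), con)
    }
    if (!is.null(spectra$rt) && !is.na(spectra$rt[i])) {
      writeLines(sprintf("RTINSECONDS=%.4f", spectra$rt[i]), con)
    }
    extra <- spectra$extra[[i]]
    if (length(extra)) {
      writeLines(paste0(names(extra), "=", unname(extra)), con)
    }
    pk <- spectra$peaks[[i]]
    if (nrow(pk)) {
      writeLines(sprintf("%.6f %.8g", pk$mz, pk$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
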