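#' Probe-level intensity matrix with probeset structure
#'
#' A \code{ProbeMatrix} holds one row per array feature (probe) and one
#' column per hybridized sample, together with the probeset each probe
#' belongs to and a scale flag.  Intensities are either raw/normalized
#' linear values (strictly positive) or log2-transformed values.
#'
#' @param intensity numeric matrix, features x samples; column names are
#'   sample ids.
#' @param probeset_id character vector, one entry per row of
#'   \code{intensity}.
#' @param probe_index integer vector of within-probeset probe positions
#'   (1-based), one entry per row.
#' @param scale either \code{"linear"} or \code{"log2"}.
#' @return An object of class \code{ProbeMatrix}.
#' @export
ProbeMatrix <- function(intensity, probeset_id, probe_index,
                        scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  probeset_id <- as.character(probeset_id)
  probe_index <- as.integer(probe_index)
  if (nrow(intensity) != length(probeset_id) ||
      nrow(intensity) != length(probe_index)) {
    stop("probe_matrix_dim_mismatch: intensity rows, probeset_id and ",
         "probe_index must have equal length")
  }
  if (anyNA(intensity)) {
    stop("probe_matrix_non_numeric: intensity contains missing values")
  }
  key <- paste(probeset_id, probe_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("probe_matrix_duplicate_probe: duplicated (probeset_id, probe_index) pair")
  }
  k <- table(probeset_id)
  if (length(unique(as.integer(k))) > 1L) {
    stop("probe_matrix_unequal_probes: probesets differ in probe count (",
         paste(range(k), collapse = "-"), ")")
  }
  if (scale == "linear" && any(intensity <= 0)) {
    stop("probe_matrix_nonpositive: linear-scale intensities must be > 0")
  }
  structure(list(intensity = intensity,
                 probeset_id = probeset_id,
                 probe_index = probe_index,
                 scale = scale),
            class = "ProbeMatrix")
}

#' @export
print.ProbeMatrix <- function(x, ...) {
  cat(sprintf("ProbeMatrix: %d probesets x %d probes, %d samples (%s scale)\n",
              length(unique(x$probeset_id)),
              probes_per_set(x), ncol(x$intensity), x$scale))
  invisible(x)
}

#' @export
dim.ProbeMatrix <- function(x) dim(x$intensity)

probes_per_set <- function(m) {
  as.integer(sum(m$probeset_id == m$probeset_id[1L]))
}

#' Sample sheet describing array hybridizations
#'
#' @param sample_id character vector of unique sample identifiers matching
#'   the intensity column names.
#' @param genotype character vector; each entry one of \code{AT} (diploid
#'   parent), \code{TC} (tetraploid parent), \code{SN} (synthetic
#'   allopolyploid) or \code{MIX} (1:1 parental RNA mix).
#' @param replicate integer vector of biological replicate numbers (>= 1).
#' @return A \code{data.frame} of class \code{SampleSheet}.
#' @export
SampleSheet <- function(sample_id, genotype, replicate) {
  sample_id <- as.character(sample_id)
  genotype <- as.character(genotype)
  replicate <- as.integer(replicate)
  if (anyDuplicated(sample_id)) {
    stop("sample_sheet_duplicate_id: sample ids must be unique")
  }
  bad <- setdiff(unique(genotype), c("AT", "TC", "SN", "MIX"))
  if (length(bad)) {
    stop("sample_sheet_bad_genotype: unknown genotype ", paste(bad, collapse = ", "))
  }
  if (any(replicate < 1L)) stop("sample_sheet_bad_replicate: replicate must be >= 1")
  out <- data.frame(sample_id = sample_id, genotype = genotype,
                    replicate = replicate, stringsAsFactors = FALSE)
  class(out) <- c("SampleSheet", "data.frame")
  out
}

sheet_samples <- function(samples, genotype) {
  samples$sample_id[samples$genotype %in% genotype]
}

#' Read a probe table and its sample sheet
#'
#' The probe table is TSV with columns \code{probeset_id},
#' \code{probe_index}, then one intensity column per sample named in the
#' sample sheet.  An optional first comment line \code{# scale=linear} or
#' \code{# scale=log2} sets the scale flag (default linear).
#'
#' @param path path to the probe table TSV.
#' @param sample_sheet_path path to the sample sheet TSV with columns
#'   \code{sample_id}, \code{genotype}, \code{replicate}.
#' @return A list with elements \code{probes} (\code{ProbeMatrix}, sample
#'   columns ordered as in the sheet) and \code{samples}
#'   (\code{SampleSheet}).
#' @export
read_probe_table <- function(path, sample_sheet_path) {
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "replicate")
  if (!all(need %in% names(sheet))) {
    stop("sample_sheet_bad_header: expected columns ", paste(need, collapse = ", "))
  }
  samples <- SampleSheet(sheet$sample_id, sheet$genotype, sheet$replicate)

  first <- readLines(path, n = 1L)
  scale <- "linear"
  if (grepl("^#", first)) {
    sc <- sub(".*scale=([a-z0-9]+).*", "\\1", first)
    if (sc %in% c("linear", "log2")) scale <- sc
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("probeset_id", "probe_index") %in% names(tab))) {
    stop("probe_table_bad_header: expected probeset_id and probe_index columns")
  }
  missing <- setdiff(samples$sample_id, names(tab))
  if (length(missing)) {
    stop("probe_table_missing_sample: sample column(s) absent: ",
         paste(missing, collapse = ", "))
  }
  vals <- tab[, samples$sample_id, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      stop("probe_table_non_numeric: column ", names(vals)[j],
           " contains non-numeric cells")
    }
  }
  pm <- ProbeMatrix(as.matrix(vals), tab$probeset_id, tab$probe_index,
                    scale = scale)
  list(probes = pm, samples = samples)
}

#' Write a probe table (and optionally a sample sheet) to TSV
#'
#' @param m a \code{ProbeMatrix}.
#' @param path output path for the probe table.
#' @param samples optional \code{SampleSheet}.
#' @param sample_sheet_path output path for the sheet when given.
#' @export
write_probe_table <- function(m, path, samples = NULL, sample_sheet_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale=", m$scale), con)
  df <- data.frame(probeset_id = m$probeset_id, probe_index = m$probe_index,
                   m$intensity, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples)) {
    utils::write.table(as.data.frame(samples), sample_sheet_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
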