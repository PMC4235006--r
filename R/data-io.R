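## On-disk interchange: delimited long tables (one row per
## frequency x level x trial) and TSV results tables with a JSON
## provenance sidecar. CSV vs TSV is autodetected from the extension.

.delimFor <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.readLong <- function(path, required) {
  sep <- .delimFor(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = TRUE)
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  for (col in required) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (is.na(v[1L]) && !length(bad)) bad <- which(is.na(v))[1L]
    if (any(is.na(v)))
      bad <- union(bad, which(is.na(v)))
    if (length(bad))
      stop("malformed value in column '", col, "' at data line ",
           bad[1L] + 1L, " of ", path)   # +1 for the header line
    raw[[col]] <- v
  }
  raw
}

#' Read a trial-wise FRA long table
#'
#' Reads a delimited long table (columns `frequency`, `level`, `trial`,
#' `count`; CSV or TSV by extension) into a validated [ResponseGrid-class].
#' Every frequency x level cell must carry the same trials; a missing cell
#' is an error, never a silent zero.
#'
#' @param path file path.
#' @param calibration optional maximum system output, dB SPL.
#' @return a [ResponseGrid-class].
#' @seealso [writeResponseGrid()]
#' @export
readResponseGrid <- function(path, calibration = NULL) {
  tab <- .readLong(path, c("frequency", "level", "trial", "count"))
  if (!isCount(tab$count))
    stop("counts must be non-negative integers: ", path)
  freqs <- sort(unique(tab$frequency))
  levels <- sort(unique(tab$level))
  trials <- sort(unique(tab$trial))
  if (!isTRUE(all.equal(trials, seq_along(trials))))
    stop("trial indices must be 1..n: ", path)
  nt <- length(trials)
  key <- paste(match(tab$frequency, freqs), match(tab$level, levels),
               tab$trial, sep = "/")
  if (anyDuplicated(key))
    stop("duplicated (frequency, level, trial) rows in ", path)
  expected <- nrow(expand.grid(seq_along(freqs), seq_along(levels))) * nt
  if (nrow(tab) != expected)
    stop("incomplete grid in ", path, ": expected ", expected,
         " rows (every frequency x level cell with trials 1..", nt,
         "), found ", nrow(tab))
  counts <- array(NA_real_, c(length(freqs), length(levels), nt))
  counts[cbind(match(tab$frequency, freqs), match(tab$level, levels),
               tab$trial)] <- tab$count
  if (anyNA(counts))
    stop("incomplete grid in ", path, ": some cells missing")
  responseGrid(stimulusGrid(freqs, levels, calibration), counts)
}

#' Write a ResponseGrid as a long table
#'
#' @param x a [ResponseGrid-class].
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
writeResponseGrid <- function(x, path) {
  stopifnot(is(x, "ResponseGrid"))
  if (!isCount(x@counts))
    stop("on-disk counts must be non-negative integers")
  d <- dim(x@counts)
  tab <- expand.grid(frequency = x@grid@frequencies,
                     level = x@grid@levels, trial = seq_len(d[3L]),
                     KEEP.OUT.ATTRS = FALSE)
  tab$count <- as.vector(x@counts)
  utils::write.table(tab, path, sep = .delimFor(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an RLF long table
#'
#' Columns `level`, `trial`, `count`; every level must carry the same
#' trials.
#'
#' @param path file path.
#' @param frequency CF tone frequency, Hz.
#' @param calibration optional maximum output, dB SPL.
#' @return a [RateLevelFunction-class].
#' @export
readRateLevelFunction <- function(path, frequency, calibration = NULL) {
  tab <- .readLong(path, c("level", "trial", "count"))
  if (!isCount(tab$count))
    stop("counts must be non-negative integers: ", path)
  levels <- sort(unique(tab$level))
  trials <- sort(unique(tab$trial))
  counts <- matrix(NA_real_, length(levels), length(trials))
  counts[cbind(match(tab$level, levels), match(tab$trial, trials))] <-
    tab$count
  if (anyNA(counts) || nrow(tab) != length(counts))
    stop("every level must carry the same trials: ", path)
  rateLevelFunction(frequency, levels, counts, calibration)
}

#' Write a RateLevelFunction as a long table
#' @param x a [RateLevelFunction-class].
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
writeRateLevelFunction <- function(x, path) {
  stopifnot(is(x, "RateLevelFunction"))
  if (!isCount(x@counts))
    stop("on-disk counts must be non-negative integers")
  tab <- expand.grid(level = x@levels, trial = seq_len(ncol(x@counts)),
                     KEEP.OUT.ATTRS = FALSE)
  tab$count <- as.vector(x@counts)
  utils::write.table(tab, path, sep = .delimFor(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read or write unit metadata as JSON
#'
#' Unit metadata travels as a JSON array of objects with fields
#' `unit_id`, `estimated_cf`, `fra_class`, `subtype`,
#' `deactivation_method`.
#'
#' @param path JSON file path.
#' @return `readUnitRecords`: a list of [UnitRecord-class] objects.
#' @export
readUnitRecords <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(u)
    unitRecord(u$unit_id, u$estimated_cf,
               fraClass = u$fra_class %||% "V",
               subtype = u$subtype %||% "",
               deactivationMethod = u$deactivation_method %||% "cooling"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readUnitRecords
#' @param units list of [UnitRecord-class] objects.
#' @return `writeUnitRecords`: `path`, invisibly.
#' @export
writeUnitRecords <- function(units, path) {
  out <- lapply(units, function(u)
    list(unit_id = u@unitId, estimated_cf = u@estimatedCF,
         fra_class = u@fraClass, subtype = u@subtype,
         deactivation_method = u@deactivationMethod))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Flatten result objects into a results table
#'
#' Turns a list of [FTCResult-class] and/or [RLFMetrics-class] objects into
#' one data frame row per result with a deterministic column order.
#'
#' @param results list of result objects (possibly named by unit).
#' @return a data frame.
#' @export
resultsTable <- function(results) {
  if (!length(results)) {
    return(data.frame(id = character(), kind = character(),
                      cf = numeric(), threshold = numeric(),
                      area_bins = numeric(), total_spikes = numeric(),
                      type_label = character(), half_max_level = numeric(),
                      di = numeric(), stringsAsFactors = FALSE))
  }
  ids <- names(results)
  if (is.null(ids)) ids <- as.character(seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (is(r, "FTCResult")) {
      data.frame(id = ids[i], kind = "fra", cf = r@cf,
                 threshold = r@threshold, area_bins = r@areaBins,
                 total_spikes = r@totalSpikes, type_label = NA_character_,
                 half_max_level = NA_real_, di = NA_real_,
                 stringsAsFactors = FALSE)
    } else if (is(r, "RLFMetrics")) {
      data.frame(id = ids[i], kind = "rlf", cf = NA_real_,
                 threshold = NA_real_, area_bins = NA_real_,
                 total_spikes = NA_real_, type_label = r@typeLabel,
                 half_max_level = r@halfMaxLevel, di = r@di,
                 stringsAsFactors = FALSE)
    } else stop("unsupported result class: ", class(r)[1L])
  })
  do.call(rbind, rows)
}

#' Write a results table with a provenance sidecar
#'
#' Writes `results` (a data frame, or a list of result objects passed
#' through [resultsTable()]) as TSV plus a `<path>.json` sidecar holding
#' provenance: a hash of the serialised configuration, the seed, and the
#' package version.
#'
#' @param results data frame or list of result objects.
#' @param path output TSV path.
#' @param config optional configuration object recorded (hashed) in the
#'   sidecar.
#' @param seed optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path, config = NULL, seed = NULL) {
  if (!is.data.frame(results)) results <- resultsTable(results)
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  sidecar <- list(
    config_hash = configHash(config),
    seed = if (is.null(seed)) NA else seed,
    package = "icresp",
    version = as.character(utils::packageVersion("icresp")),
    columns = names(results), rows = nrow(results))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read back a results table written by [writeResults()]
#' @param path TSV path.
#' @return a data frame.
#' @export
readResults <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Deterministic hash of a configuration object
#'
#' Serialises the object canonically (version 2 serialisation of its
#' deparsed form) and returns a short hex digest, so two runs with the same
#' configuration carry the same provenance hash.
#'
#' @param config any R object (or `NULL`).
#' @return hex string.
#' @export
configHash <- function(config) {
  if (is.null(config)) return("none")
  txt <- paste(deparse(config, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(txt)
  ## rolling polynomial hash mod a prime; exact in double precision
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}
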