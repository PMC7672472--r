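#' Construct and validate a plate experiment
#'
#' A plate experiment is a long-format tibble of fluorescence reads with one
#' row per (aptamer, ligand, concentration, replicate, time) and a
#' provenance attribute. Validation enforces: matching column set, strictly
#' increasing times within each well, non-negative fluorescence, no
#' duplicate (well, time) rows, and a ligand-free control (`concentration_uM
#' = 0`) for every aptamer that has a ligand condition.
#'
#' @param data Data frame with columns `aptamer_id`, `ligand_id`,
#'   `concentration_uM`, `replicate`, `time_min`, `fluorescence_au`.
#' @param provenance Named list of free-form metadata (instrument, seed,
#'   config hash, ...).
#' @return The validated tibble with class `plate_experiment`.
#' @export
plate_experiment <- function(data, provenance = list()) {
  data <- tibble::as_tibble(data)
  required <- c("aptamer_id", "ligand_id", "concentration_uM", "replicate",
                "time_min", "fluorescence_au")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[required]
  data$replicate <- as.integer(data$replicate)
  if (any(data$fluorescence_au < 0, na.rm = TRUE)) {
    stop("fluorescence must be >= 0", call. = FALSE)
  }
  key <- paste(data$aptamer_id, data$ligand_id, data$concentration_uM,
               data$replicate, sep = "\r")
  dup <- duplicated(paste(key, data$time_min, sep = "\r"))
  if (any(dup)) {
    bad <- data[which(dup)[1], ]
    stop("duplicate read for well (", bad$aptamer_id, ", ", bad$ligand_id,
         ", ", bad$concentration_uM, " uM, replicate ", bad$replicate,
         ") at t = ", bad$time_min, " min", call. = FALSE)
  }
  for (k in unique(key)) {
    tt <- data$time_min[key == k]
    if (is.unsorted(tt, strictly = TRUE)) {
      # tolerate unsorted input but reject ties; callers get sorted output
      if (anyDuplicated(tt)) {
        stop("non-increasing times within well ",
             gsub("\r", "/", k), call. = FALSE)
      }
    }
  }
  data <- dplyr::arrange(data, .data$aptamer_id, .data$ligand_id,
                         .data$concentration_uM, .data$replicate,
                         .data$time_min)
  with_ligand <- unique(data$aptamer_id[data$concentration_uM > 0])
  with_control <- unique(data$aptamer_id[data$concentration_uM == 0])
  orphans <- setdiff(with_ligand, with_control)
  if (length(orphans) > 0) {
    stop("aptamer(s) without a ligand-free control: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  structure(data, class = c("plate_experiment", class(tibble::tibble())),
            provenance = provenance)
}

#' Read a long-format time-course CSV into a plate experiment
#'
#' Expected schema: `aptamer_id, ligand_id, concentration_uM, replicate,
#' time_min, fluorescence_au` (RFC-4180 CSV, UTF-8, "." decimal). Rows are
#' grouped into wells by (aptamer, ligand, concentration, replicate) and
#' sorted by time; all plate invariants are validated.
#'
#' @param path Path to the CSV file.
#' @return A [plate_experiment()].
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  plate_experiment(data, provenance = list(source = path))
}

#' Write a plate experiment to a long-format time-course CSV
#'
#' Rows are written in the plate's canonical sort order so that identical
#' experiments produce byte-identical files.
#'
#' @param plate A [plate_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(plate, path) {
  stopifnot(inherits(plate, "plate_experiment"))
  readr::write_csv(tibble::as_tibble(plate), path, progress = FALSE)
  invisible(path)
}

#' Read an aptamer panel from FASTA
#'
#' Headers carry whitespace-separated `key=value` attributes after the id,
#' e.g. `>MA-46 protected_length=41`. The sequence length defines the full
#' length N. A record without `protected_length` defaults to `P = N - 5`,
#' reflecting the few (3-6) 5'-terminal nucleotides typically trimmed before
#' digestion stalls.
#'
#' @param path Path to a FASTA file.
#' @return A list of [aptamer_spec()] objects (empty, with a warning, for an
#'   empty file).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">MA-46 protected_length=41",
#'              paste(rep("ACGT", 11), collapse = ""), ""), fa)
#' @export
read_aptamer_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    warning("empty aptamer panel: ", path, call. = FALSE)
    return(list())
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate aptamer ids in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    seq_i <- as.character(seqs[[i]])
    n <- nchar(seq_i)
    attrs <- parse_header_attrs(headers[i])
    p <- if ("protected_length" %in% names(attrs)) {
      as.integer(attrs[["protected_length"]])
    } else {
      n - 5L
    }
    if (is.na(p) || p > n) {
      stop("protected_length (", attrs[["protected_length"]],
           ") exceeds sequence length (", n, ") for ", ids[i], call. = FALSE)
    }
    out[[i]] <- aptamer_spec(ids[i], full_length_nt = n,
                             protected_length_nt = p, sequence = seq_i)
  }
  names(out) <- ids
  out
}

parse_header_attrs <- function(header) {
  tokens <- strsplit(header, "\\s+")[[1]]
  kv <- tokens[grepl("=", tokens, fixed = TRUE)]
  if (length(kv) == 0) return(character(0))
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}

#' Read a binding table CSV
#'
#' Schema: `aptamer_id, ligand_id, kd_app_uM` with `"NB"` as the non-binder
#' sentinel (mapped to `Inf`). Optional columns `concentration_uM` and
#' `dye_artifact_factor` are passed through when present.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `kd_app` numeric (uM, `Inf` = non-binder).
#' @export
read_binding_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            kd_app_uM = readr::col_character(),
                            .default = readr::col_guess()))
  required <- c("aptamer_id", "ligand_id", "kd_app_uM")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  kd <- ifelse(toupper(trimws(data$kd_app_uM)) == "NB", Inf,
               suppressWarnings(as.numeric(data$kd_app_uM)))
  if (any(is.na(kd))) {
    stop("unparseable kd_app_uM value(s): ",
         paste(unique(data$kd_app_uM[is.na(kd)]), collapse = ", "),
         call. = FALSE)
  }
  data$kd_app <- kd
  data$kd_app_uM <- NULL
  key <- paste(data$aptamer_id, data$ligand_id)
  if (anyDuplicated(key)) {
    stop("duplicate (aptamer, ligand) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Write result tables as CSV files
#'
#' Writes one CSV per named table into `out_dir`. Producers in this package
#' emit tables in a deterministic column order and row sort, so repeated
#' runs on identical inputs produce byte-identical files. Empty tables
#' yield header-only files.
#'
#' @param results Named list of data frames (e.g. `resistance`,
#'   `cross_reactivity`, `screen_calls`, `fits`).
#' @param out_dir Output directory, created if absent.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(is.list(results), length(names(results)) == length(results),
            all(nzchar(names(results))))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- character(0)
  for (nm in names(results)) {
    tab <- tibble::as_tibble(results[[nm]])
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tab, path, progress = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}
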