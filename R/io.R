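# Delimited-text readers and writers. Units are explicit in headers
# (amol, min, ppm); decimal separator is always '.'.

.TRANSITION_COLS <- c("peptide", "protein", "precursor_mz", "charge",
                      "fragment", "fragment_mz", "label", "is_amount_amol")

#' Read a transition list
#'
#' Skyline-style transition report: one row per (peptide, label, fragment).
#' Required columns: peptide, protein, precursor_mz, charge, fragment,
#' fragment_mz, label, is_amount_amol (blank allowed on light rows). Extra
#' columns are preserved.
#'
#' @param path CSV file path.
#' @return Validated tibble of transitions.
#' @export
read_transition_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(.TRANSITION_COLS, names(raw))
  if (length(missing)) {
    stop("transition list is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("precursor_mz", "charge", "fragment_mz", "is_amount_amol")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & nzchar(raw[[col]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed number in column '%s', data row(s) %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    }
    raw[[col]] <- v
  }
  if (!all(raw$label %in% c("light", "heavy"))) {
    stop("label column must be 'light' or 'heavy'", call. = FALSE)
  }
  no_is <- raw$label == "heavy" & is.na(raw$is_amount_amol)
  if (any(no_is)) {
    stop("heavy rows must carry is_amount_amol (missing in row(s) ",
         paste(which(no_is), collapse = ", "), ")", call. = FALSE)
  }
  raw
}

#' Write a transition list for a panel
#'
#' @param panel A `prm_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(panel, path) {
  tbl <- panel |>
    dplyr::mutate(fr = .data$fragments) |>
    tidyr::unnest("fr") |>
    dplyr::transmute(
      peptide = .data$peptide, protein = .data$protein,
      precursor_mz = .data$precursor_mz, charge = .data$charge,
      fragment = .data$fragment, fragment_mz = .data$mz,
      label = .data$label,
      is_amount_amol = ifelse(.data$label == "heavy", .data$is_amount, NA)
    )
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Write an acquisition to long-format CSV (+ truth sidecar)
#'
#' Columns: `scan_rt_min`, `peptide`, `label`, `fragment`, `measured_mz`,
#' `intensity`. The seed, settings and truth amounts go to a YAML sidecar
#' `<path>.truth.yaml` so any run can be reproduced.
#'
#' @param acquisition A `prm_acquisition`.
#' @param path Output CSV path.
#' @param truth Write the sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_acquisition <- function(acquisition, path, truth = TRUE) {
  acquisition$scans |>
    dplyr::transmute(scan_rt_min = .data$rt, peptide = .data$peptide,
                     label = .data$label, fragment = .data$fragment,
                     measured_mz = .data$measured_mz,
                     intensity = .data$intensity) |>
    readr::write_csv(path)
  if (truth && !is.null(acquisition$truth)) {
    side <- list(
      seed = acquisition$truth$seed,
      settings = unclass(acquisition$settings),
      amounts = as.list(stats::setNames(
        acquisition$truth$amounts$amol,
        paste(acquisition$truth$amounts$peptide,
              acquisition$truth$amounts$label, sep = "/")
      ))
    )
    yaml::write_yaml(side, paste0(path, ".truth.yaml"))
  }
  invisible(path)
}

#' Read chromatographic data
#'
#' `"long-csv"` reads the native long format written by
#' [write_acquisition()]; `"mzml"` reads the chromatogram list of an mzML
#' file (via the mzR package), mapping chromatogram ids of the form
#' `peptide/label/fragment` onto the same structure.
#'
#' @param path Input file.
#' @param format `"long-csv"` or `"mzml"`.
#' @return An acquisition-equivalent list with `scans` and `scan_times`
#'   (settings/truth attached from the sidecar when present).
#' @export
read_chromatograms <- function(path, format = c("long-csv", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  scans <- if (format == "long-csv") read_long_csv(path) else read_mzml(path)
  acq <- list(
    scans = scans,
    scan_times = dplyr::distinct(scans, .data$peptide, .data$label, .data$rt),
    settings = NULL, truth = NULL
  )
  side <- paste0(path, ".truth.yaml")
  if (format == "long-csv" && file.exists(side)) {
    meta <- yaml::read_yaml(side)
    acq$settings <- do.call(acquisition_settings, meta$settings)
    amt <- tibble::tibble(key = names(meta$amounts),
                          amol = as.numeric(unlist(meta$amounts))) |>
      tidyr::separate("key", c("peptide", "label"), sep = "/")
    acq$truth <- structure(list(amounts = amt, interferents = NULL,
                                seed = meta$seed), class = "prm_truth")
  }
  structure(acq, class = "prm_acquisition")
}

read_long_csv <- function(path) {
  need <- c("scan_rt_min", "peptide", "label", "fragment", "measured_mz",
            "intensity")
  tbl <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("unreadable file: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop("chromatogram CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(tbl)
  if (nrow(probs)) {
    stop(sprintf("malformed chromatogram CSV at row %d, col %d",
                 probs$row[1], probs$col[1]), call. = FALSE)
  }
  tbl |>
    dplyr::transmute(rt = .data$scan_rt_min, peptide = .data$peptide,
                     label = .data$label, fragment = .data$fragment,
                     true_mz = NA_real_, measured_mz = .data$measured_mz,
                     intensity = .data$intensity)
}

read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML support requires the mzR package", call. = FALSE)
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  n <- mzR::nChrom(h)
  if (n < 1) stop("mzML file has no chromatogram list", call. = FALSE)
  hdr <- mzR::chromatogramHeader(h)
  ids <- hdr$chromatogramId
  purrr::map_dfr(seq_len(n), function(i) {
    ch <- mzR::chromatogram(h, i)
    parts <- strsplit(ids[i], "/", fixed = TRUE)[[1]]
    if (length(parts) != 3) return(NULL)  # e.g. a TIC chromatogram
    tibble::tibble(rt = ch[, 1], peptide = parts[1], label = parts[2],
                   fragment = parts[3], true_mz = NA_real_,
                   measured_mz = NA_real_, intensity = ch[, 2])
  })
}

#' Write an acquisition's traces as chromatogram-mzML
#'
#' Minimal mzML 1.1 writer for chromatogram lists (64-bit, uncompressed),
#' with chromatogram ids `peptide/label/fragment`. Intended for
#' interoperability tests and export; spectra are not written.
#'
#' @param acquisition A `prm_acquisition`.
#' @param path Output .mzML path.
#' @return `path`, invisibly.
#' @export
write_mzml_chromatograms <- function(acquisition, path) {
  traces <- acquisition$scans |>
    dplyr::group_by(.data$peptide, .data$label, .data$fragment)
  keys <- dplyr::group_keys(traces)
  grps <- dplyr::group_split(traces)

  enc <- function(x) {
    # single-line base64: readers reject whitespace inside <binary>
    gsub("[\r\n]", "",
         jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                       endian = "little")))
  }
  chroms <- purrr::map_chr(seq_along(grps), function(i) {
    g <- grps[[i]][order(grps[[i]]$rt), ]
    id <- paste(keys$peptide[i], keys$label[i], keys$fragment[i], sep = "/")
    np <- nrow(g)
    rt64 <- enc(g$rt)
    in64 <- enc(g$intensity)
    paste0(
      sprintf('<chromatogram index="%d" id="%s" defaultArrayLength="%d">',
              i - 1L, id, np),
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(rt64)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000595" name="time array" unitAccession="UO:0000031" unitName="minute"/>',
      '<binary>', rt64, '</binary></binaryDataArray>',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(in64)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitAccession="MS:1000131" unitName="number of detector counts"/>',
      '<binary>', in64, '</binary></binaryDataArray>',
      '</binaryDataArrayList></chromatogram>'
    )
  })
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000810" name="ion current chromatogram"/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="prmquant" version="0.1.0"/></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="prmquant">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('<chromatogramList count="%d" defaultDataProcessingRef="dp1">',
            length(chroms)),
    paste(chroms, collapse = ""),
    '</chromatogramList></run></mzML>'
  )
  writeLines(xml, path)
  invisible(path)
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    id <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1),
                   collapse = "")
    stats::setNames(toupper(seqs), id)
  }
}

#' Assemble a run configuration
#'
#' Bundles acquisition settings, acceptance thresholds and quantification
#' constants with the run seed; round-trips losslessly through YAML.
#'
#' @param settings [acquisition_settings()].
#' @param thresholds [acceptance_thresholds()].
#' @param loq_max_dev LOQ deviation rule, percent.
#' @param loaded_peptide_ug,protein_per_cell_ng,avogadro Quantification
#'   constants.
#' @param seed Integer seed.
#' @return A `prm_config` list.
#' @export
run_config <- function(settings = acquisition_settings(),
                       thresholds = acceptance_thresholds(),
                       loq_max_dev = 20, loaded_peptide_ug = 1,
                       protein_per_cell_ng = 0.20, avogadro = 6.022e23,
                       seed = 1L) {
  stopifnot(loq_max_dev > 0, loaded_peptide_ug > 0, protein_per_cell_ng > 0)
  structure(list(settings = settings, thresholds = thresholds,
                 loq_max_dev = loq_max_dev,
                 loaded_peptide_ug = loaded_peptide_ug,
                 protein_per_cell_ng = protein_per_cell_ng,
                 avogadro = avogadro, seed = as.integer(seed)),
            class = "prm_config")
}

#' @rdname run_config
#' @param config A `prm_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  out <- config
  out$settings <- unclass(out$settings)
  yaml::write_yaml(unclass(out), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(settings = do.call(acquisition_settings, raw$settings),
             thresholds = do.call(acceptance_thresholds, raw$thresholds),
             loq_max_dev = raw$loq_max_dev,
             loaded_peptide_ug = raw$loaded_peptide_ug,
             protein_per_cell_ng = raw$protein_per_cell_ng,
             avogadro = raw$avogadro, seed = raw$seed)
}
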