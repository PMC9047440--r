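#' Read MRM/SRM chromatograms for defined metabolites from an mzML file
#'
#' Chromatograms are matched to the metabolite transitions by precursor and
#' product m/z within `mz_tolerance` (and polarity when both sides declare
#' one). Times are converted to minutes regardless of the unit stored in the
#' file. Transitions without a matching chromatogram are reported with a
#' warning and simply absent from the result; a transition matching more
#' than one chromatogram raises an ambiguity error.
#'
#' @param path Path to an mzML file containing SRM chromatograms.
#' @param metabolites Metabolite definition tibble from
#'   [read_metabolite_db()] (columns `metabolite`, `quant_precursor`,
#'   `quant_product`, optional `qual_*`, `istd_*`, `polarity`).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param mz_tolerance Matching tolerance in Th on both precursor and
#'   product m/z (default 0.05).
#' @return Tibble with columns `sample_id`, `metabolite`, `role`
#'   (`quantifier`/`qualifier`/`istd`) and `chromatogram` (list of
#'   `time`/`intensity` tibbles, time in minutes).
#' @export
read_mrm_mzml <- function(path, metabolites, sample_id = NULL, mz_tolerance = 0.05) {
  if (!requireNamespace("mzR", quietly = TRUE)) abort("Package 'mzR' is required.")
  if (!file.exists(path)) abort(sprintf("mzML file not found: %s", path))
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) abort(sprintf("Cannot parse mzML file %s: %s",
                                                   path, conditionMessage(e))))
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::chromatogramHeader(ms)
  if (nrow(hdr) == 0L) abort(sprintf("No chromatograms in mzML file %s", path))
  secs <- time_unit_is_seconds(path, nrow(hdr))

  get_chrom <- function(i) {
    d <- mzR::chromatogram(ms, i)
    if (is.list(d) && !is.data.frame(d)) d <- d[[1L]]
    tt <- as.numeric(d[[1L]])
    if (isTRUE(secs[i])) tt <- tt / 60
    tibble(time = tt, intensity = pmax(0, as.numeric(d[[2L]])))
  }

  roles <- transition_roles(metabolites)
  out <- vector("list", nrow(roles))
  for (r in seq_len(nrow(roles))) {
    hit <- which(abs(hdr$precursorIsolationWindowTargetMZ - roles$precursor_mz[r]) <= mz_tolerance &
                 abs(hdr$productIsolationWindowTargetMZ - roles$product_mz[r]) <= mz_tolerance)
    if (length(hit) > 1L && !is.na(roles$polarity[r]) && "polarity" %in% names(hdr)) {
      want <- if (roles$polarity[r] == "negative") 0L else 1L
      hit2 <- hit[hdr$polarity[hit] %in% want]
      if (length(hit2) >= 1L) hit <- hit2
    }
    if (length(hit) == 0L) {
      warn(sprintf("No chromatogram for %s %s (%.4g -> %.4g) in %s",
                   roles$metabolite[r], roles$role[r],
                   roles$precursor_mz[r], roles$product_mz[r], basename(path)))
      next
    }
    if (length(hit) > 1L) {
      abort(sprintf("Ambiguous transition match for %s %s (%.4g -> %.4g): chromatograms %s",
                    roles$metabolite[r], roles$role[r], roles$precursor_mz[r],
                    roles$product_mz[r],
                    paste(hdr$chromatogramId[hit], collapse = ", ")))
    }
    out[[r]] <- tibble(sample_id = sample_id, metabolite = roles$metabolite[r],
                       role = roles$role[r],
                       chromatogram = list(get_chrom(hdr$chromatogramIndex[hit])))
  }
  list_rbind(out[!vapply(out, is.null, logical(1))])
}

# long table of defined transitions: metabolite, role, precursor, product
transition_roles <- function(metabolites) {
  rows <- list()
  for (i in seq_len(nrow(metabolites))) {
    m <- metabolites[i, ]
    pol <- if ("polarity" %in% names(m)) m$polarity else NA_character_
    add <- function(role, pre, pro) {
      if (is.na(pre) || is.na(pro)) return(NULL)
      tibble(metabolite = m$metabolite, role = role,
             precursor_mz = pre, product_mz = pro, polarity = pol)
    }
    rows <- c(rows, list(
      add("quantifier", m$quant_precursor, m$quant_product),
      if (all(c("qual_precursor", "qual_product") %in% names(m)))
        add("qualifier", m$qual_precursor, m$qual_product),
      if (all(c("istd_precursor", "istd_product") %in% names(m)))
        add("istd", m$istd_precursor, m$istd_product)
    ))
  }
  list_rbind(rows[!vapply(rows, is.null, logical(1))])
}

# per-chromatogram flag: is the time array stored in seconds?
# mzR returns the stored values unchanged, so the unit accession
# (UO:0000010 second vs UO:0000031 minute) is read from the XML directly.
time_unit_is_seconds <- function(path, n) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) NULL)
  out <- rep(FALSE, n)
  if (is.null(doc)) return(out)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")
  chroms <- xml2::xml_find_all(doc, ".//m:chromatogram", ns)
  for (i in seq_along(chroms)) {
    u <- xml2::xml_find_first(
      chroms[[i]],
      ".//m:binaryDataArray/m:cvParam[@accession='MS:1000595']", ns)
    if (!inherits(u, "xml_missing") &&
        identical(xml2::xml_attr(u, "unitAccession"), "UO:0000010")) {
      idx <- as.integer(xml2::xml_attr(chroms[[i]], "index")) + 1L
      if (!is.na(idx) && idx >= 1L && idx <= n) out[idx] <- TRUE else out[i] <- TRUE
    }
  }
  out
}

#' Read a metabolite definition table
#'
#' CSV/TSV is the canonical dialect; `.xlsx` is read through the readxl
#' package when installed. Mandatory columns: `metabolite`,
#' `quant_precursor`, `quant_product`, `expected_rt`. Optional:
#' `qual_precursor`/`qual_product`, `istd_precursor`/`istd_product`,
#' `polarity`, `expected_ratio`, `db_id`.
#'
#' @param path Path to the table.
#' @return Tibble with one row per metabolite, file order preserved;
#'   absent optional columns are filled with `NA`.
#' @export
read_metabolite_db <- function(path) {
  if (!file.exists(path)) abort(sprintf("Metabolite DB not found: %s", path))
  tb <- read_any_table(path)
  mandatory <- c("metabolite", "quant_precursor", "quant_product", "expected_rt")
  miss <- setdiff(mandatory, names(tb))
  if (length(miss)) abort(sprintf("Metabolite DB is missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  optional <- c("qual_precursor", "qual_product", "istd_precursor",
                "istd_product", "polarity", "expected_ratio", "db_id")
  for (col in optional) if (!col %in% names(tb)) tb[[col]] <- NA
  num <- c("quant_precursor", "quant_product", "qual_precursor", "qual_product",
           "istd_precursor", "istd_product", "expected_rt", "expected_ratio")
  for (col in num) tb[[col]] <- suppressWarnings(as.numeric(tb[[col]]))
  bad_rt <- which(!is.finite(tb$expected_rt) | tb$expected_rt <= 0)
  if (length(bad_rt)) abort(sprintf("Non-positive expected_rt in row(s): %s",
                                    paste(bad_rt, collapse = ", ")))
  bad_ratio <- which(!is.na(tb$expected_ratio) & tb$expected_ratio <= 0)
  if (length(bad_ratio)) abort(sprintf("Non-positive expected_ratio in row(s): %s",
                                       paste(bad_ratio, collapse = ", ")))
  as_tibble(tb[, c(mandatory[1:3], "qual_precursor", "qual_product",
                   "istd_precursor", "istd_product", "polarity",
                   "expected_rt", "expected_ratio", "db_id")])
}

read_any_table <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("Reading xlsx requires the readxl package; use CSV/TSV instead.")
    }
    return(as_tibble(readxl::read_excel(path)))
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Read the sample metadata flat file
#'
#' A TSV (or CSV) with one row per sample; the only mandatory column is
#' `sample_id` (a column named `sample` is accepted and renamed). All other
#' columns are carried along as free metadata.
#'
#' @param path Path to the flat file.
#' @return Tibble, one row per sample, order preserved.
#' @export
read_sample_info <- function(path) {
  if (!file.exists(path)) abort(sprintf("Sample info file not found: %s", path))
  tb <- read_any_table(path)
  if (!"sample_id" %in% names(tb) && "sample" %in% names(tb)) {
    names(tb)[names(tb) == "sample"] <- "sample_id"
  }
  if (!"sample_id" %in% names(tb)) abort("Sample info needs a `sample_id` column.")
  if (anyDuplicated(tb$sample_id)) abort("Duplicate sample_id in sample info.")
  as_tibble(tb)
}

#' Write the result tables of a processed batch
#'
#' Emits the primary table (reported quantifier peak areas; unreported cells
#' empty) plus four alternative representations: raw area, raw height, and
#' both normalised to the \eqn{^{13}}C internal-standard qualifier.
#' Matrix layout metabolites x samples with deterministic order (metabolite
#' DB order, sample batch order).
#'
#' @param result An `mrm_batch` object from [process_batch()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"tsv"`.
#' @return Invisible character vector of the five file paths.
#' @export
write_peak_tables <- function(result, dir, format = c("csv", "tsv")) {
  stopifnot(inherits(result, "mrm_batch"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  peaks <- result$peaks
  mets <- unique(result$metabolites$metabolite)
  samp <- result$sample_ids

  to_matrix <- function(value_col, mask = NULL) {
    wide <- matrix(NA_character_, nrow = length(mets), ncol = length(samp),
                   dimnames = list(mets, samp))
    val <- peaks[[value_col]]
    if (!is.null(mask)) val[!peaks[[mask]]] <- NA_real_
    wide[cbind(match(peaks$metabolite, mets), match(peaks$sample_id, samp))] <-
      fmt_sig17(val)
    as_tibble(wide, rownames = "metabolite")
  }
  tables <- list(
    peaks_reported = to_matrix("area", mask = "reported"),
    area_raw = to_matrix("area"),
    height_raw = to_matrix("height"),
    area_istd = to_matrix("area_istd"),
    height_istd = to_matrix("height_istd")
  )
  ext <- format
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".", ext))
    writer(tables[[nm]], p, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

# 17 significant digits: the shortest printf format guaranteed to round-trip
# an IEEE double exactly, so write -> read -> write is bit-stable
fmt_sig17 <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- is.finite(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}

#' Read back a peak table written by [write_peak_tables()]
#'
#' @param path Path to one of the emitted CSV/TSV matrices.
#' @return Tibble with `metabolite` and one numeric column per sample;
#'   empty cells become `NA`.
#' @export
read_peak_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # base strtod parsing is correctly rounded, which the bit-exact
  # write -> read round-trip of the 17-digit format relies on
  tb <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          na.strings = c("", "NA"), colClasses = "character",
                          stringsAsFactors = FALSE)
  for (col in names(tb)[-1L]) tb[[col]] <- as.numeric(tb[[col]])
  as_tibble(tb)
}

#' Write a synthetic batch to mzML files
#'
#' Serialises every sample of a synthetic batch as a standalone mzML file
#' with one SRM chromatogram per transition (uncompressed 64-bit arrays,
#' time in minutes), so the mzML reader can be exercised end-to-end without
#' instrument data.
#'
#' @param batch An `mrm_sim_batch` from [generate_batch()].
#' @param dir Output directory.
#' @return Invisible character vector of written file paths.
#' @export
write_mrm_mzml <- function(batch, dir) {
  stopifnot(inherits(batch, "mrm_sim_batch"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mets <- batch$metabolites
  paths <- character(0)
  for (s in batch$samples$sample_id) {
    d <- batch$chromatograms[batch$chromatograms$sample_id == s, ]
    entries <- list()
    for (i in seq_len(nrow(d))) {
      m <- mets[mets$metabolite == d$metabolite[i], ]
      mz <- switch(d$role[i],
        quantifier = c(m$quant_precursor, m$quant_product),
        qualifier = c(m$qual_precursor, m$qual_product),
        istd = c(m$istd_precursor, m$istd_product))
      ch <- d$chromatogram[[i]]
      entries[[length(entries) + 1L]] <- list(
        id = sprintf("SRM SIC Q1=%g Q3=%g", mz[1L], mz[2L]),
        q1 = mz[1L], q3 = mz[2L], polarity = m$polarity,
        times = ch$time, intensities = ch$intensity)
    }
    p <- file.path(dir, paste0(s, ".mzML"))
    write_mzml_file(p, entries)
    paths <- c(paths, p)
  }
  invisible(paths)
}

b64_doubles <- function(x) {
  gsub("[\r\n]", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8L, endian = "little")))
}

mzml_chrom_entry <- function(idx, e, time_unit = c("minute", "second")) {
  time_unit <- match.arg(time_unit)
  unit_acc <- if (time_unit == "minute") "UO:0000031" else "UO:0000010"
  pol <- if (identical(e$polarity, "negative")) {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  }
  tb <- b64_doubles(e$times)
  ib <- b64_doubles(e$intensities)
  sprintf('    <chromatogram index="%d" id="%s" defaultArrayLength="%d">
      <cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/>
      %s
      <precursor><isolationWindow><cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/></isolationWindow><activation><cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/></activation></precursor>
      <product><isolationWindow><cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/></isolationWindow></product>
      <binaryDataArrayList count="2">
        <binaryDataArray encodedLength="%d">
          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
          <cvParam cvRef="MS" accession="MS:1000595" name="time array" value="" unitCvRef="UO" unitAccession="%s" unitName="%s"/>
          <binary>%s</binary>
        </binaryDataArray>
        <binaryDataArray encodedLength="%d">
          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
          <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
          <binary>%s</binary>
        </binaryDataArray>
      </binaryDataArrayList>
    </chromatogram>', idx, e$id, length(e$times), pol, e$q1, e$q3,
    nchar(tb), unit_acc, time_unit, tb, nchar(ib), ib)
}

write_mzml_file <- function(path, entries, time_unit = "minute") {
  body <- paste(vapply(seq_along(entries), function(i) {
    mzml_chrom_entry(i - 1L, entries[[i]], time_unit)
  }, character(1)), collapse = "\n")
  xml <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>
  </cvList>
  <fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/></fileContent></fileDescription>
  <softwareList count="1"><software id="mrmpick" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="mrmpick"/></software></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000870" name="4000 QTRAP" value=""/></instrumentConfiguration></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="mrmpick"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <chromatogramList count="%d" defaultDataProcessingRef="dp1">
%s
    </chromatogramList>
  </run>
</mzML>', length(entries), body)
  writeLines(xml, path)
  invisible(path)
}
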