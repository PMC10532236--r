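# CSV dialect: comma-delimited, mandatory header, quoted strings, decimal
# point. Vendor exports vary, so parse_instrument_csv accepts a column map
# translating renamed headers onto the canonical schema.

.instrument_required <- c("barcode", "role", "analyte_area", "istd_area")

#' Parse an instrument batch export
#'
#' Reads the delimited table exported from the mass spectrometer (one row
#' per injected specimen: barcode, sample role, analyte and internal
#' standard peak areas, optional nominal concentration for calibrators and
#' QCs). Rows failing validation (non-numeric or non-positive internal
#' standard area, negative analyte area, unknown role) are collected as
#' warnings, never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named character vector translating vendor
#'   headers to canonical names, e.g.
#'   `c(barcode = "Sample ID", analyte_area = "Area")`.
#' @param batch_id Batch identifier; defaults to the file name.
#'
#' @return A list of class `"instrument_batch"` with `batch_id`, `samples`
#'   (validated rows, with `valid` and `row_flag` columns), `warnings`
#'   (character), and `source`.
#' @export
parse_instrument_csv <- function(path, column_map = NULL, batch_id = NULL) {
  if (!file.exists(path)) stop("instrument file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(.instrument_required, names(raw))
  if (length(missing_cols))
    stop("instrument file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"nominal_concentration" %in% names(raw))
    raw$nominal_concentration <- NA_real_

  raw$analyte_area <- suppressWarnings(as.numeric(raw$analyte_area))
  raw$istd_area <- suppressWarnings(as.numeric(raw$istd_area))
  raw$nominal_concentration <-
    suppressWarnings(as.numeric(raw$nominal_concentration))

  warnings <- character(0)
  flag <- rep("", nrow(raw))
  bad_istd <- is.na(raw$istd_area) | raw$istd_area <= 0
  bad_area <- is.na(raw$analyte_area) | raw$analyte_area < 0
  bad_role <- !raw$role %in% c("blank", "calibrator", "qc", "patient")
  flag[bad_istd] <- "invalid_istd_area"
  flag[bad_area & flag == ""] <- "invalid_analyte_area"
  flag[bad_role & flag == ""] <- "unknown_role"
  for (i in which(flag != ""))
    warnings <- c(warnings,
                  sprintf("row %d (barcode %s): %s", i, raw$barcode[i],
                          flag[i]))
  pat <- raw$barcode[raw$role == "patient" & flag == ""]
  if (anyDuplicated(pat)) {
    dups <- unique(pat[duplicated(pat)])
    stop("duplicate patient barcode(s) within batch: ",
         paste(dups, collapse = ", "))
  }
  raw$valid <- flag == ""
  raw$row_flag <- flag
  structure(list(batch_id = if (is.null(batch_id)) basename(path) else batch_id,
                 samples = raw, warnings = warnings, source = path),
            class = "instrument_batch")
}

#' Write an instrument batch table to CSV
#'
#' Counterpart of [parse_instrument_csv()]; used by the simulator and for
#' round-trip testing. Deterministic: fixed column order, fixed quoting,
#' trailing newline.
#'
#' @param batch Data frame with the canonical instrument columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_instrument_csv <- function(batch, path) {
  cols <- c("barcode", "role", "nominal_concentration",
            "analyte_area", "istd_area")
  if (!"nominal_concentration" %in% names(batch))
    batch$nominal_concentration <- NA_real_
  utils::write.csv(batch[, cols], path, row.names = FALSE, quote = TRUE,
                   eol = "\n", na = "")
  invisible(path)
}

#' Parse a test-order table
#'
#' One row per patient: identifier, dose (either `dose_mg` directly or
#' `injected_volume_ml` with `formulation_mg_per_ml`; volume entry is the
#' default clinic workflow), body surface area, ISO 8601 injection
#' timestamp, and one barcode/timestamp pair per protocol draw
#' (`barcode_1`/`time_1`, ...). Orders whose draw count differs from the
#' configured protocol, whose draws precede the injection, or which lack a
#' BSA are rejected.
#'
#' @param path Path to the orders CSV.
#' @param config A [gfr_config()]; `n_draws` sets the expected draw count.
#' @return A list of `"test_order"` objects: `patient_id`, `dose_mg`,
#'   `bsa_m2`, `injection_time` (POSIXct), `draw_times` (POSIXct),
#'   `draw_barcodes`.
#' @export
parse_order_csv <- function(path, config = gfr_config()) {
  if (!file.exists(path)) stop("orders file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(raw)) stop("orders file needs patient_id")
  lapply(seq_len(nrow(raw)), function(i) {
    row <- raw[i, ]
    order_error <- function(...)
      stop("order ", row$patient_id, ": ", ..., call. = FALSE)

    dose <- suppressWarnings(as.numeric(row$dose_mg))
    if (is.null(row$dose_mg) || is.na(dose)) {
      vol <- suppressWarnings(as.numeric(row$injected_volume_ml))
      fc <- suppressWarnings(as.numeric(row$formulation_mg_per_ml))
      if (is.na(fc)) fc <- config$formulation_concentration
      if (is.na(vol) || vol <= 0)
        order_error("no dose: need dose_mg or injected_volume_ml")
      dose <- vol * fc
    }
    if (dose <= 0) order_error("dose must be > 0")

    bsa <- suppressWarnings(as.numeric(row$bsa_m2))
    if (is.null(row$bsa_m2) || is.na(bsa))
      order_error("missing BSA")

    inj <- parse_iso_time(row$injection_time)
    if (is.na(inj)) order_error("unparseable injection_time")

    bc_cols <- grep("^barcode_[0-9]+$", names(raw), value = TRUE)
    tm_cols <- grep("^time_[0-9]+$", names(raw), value = TRUE)
    barcodes <- unlist(row[bc_cols], use.names = FALSE)
    times_raw <- unlist(row[tm_cols], use.names = FALSE)
    keep <- !is.na(barcodes) & barcodes != ""
    barcodes <- barcodes[keep]
    times_raw <- times_raw[keep]
    if (length(barcodes) != config$n_draws)
      order_error("expected ", config$n_draws, " draws, found ",
                  length(barcodes))
    draws <- parse_iso_time(times_raw)
    if (anyNA(draws)) order_error("unparseable draw time(s)")
    if (any(draws <= inj))
      order_error("draw time(s) not after injection")
    if (is.unsorted(as.numeric(draws), strictly = TRUE))
      order_error("draw times not strictly increasing")

    structure(list(patient_id = row$patient_id, dose_mg = dose,
                   bsa_m2 = bsa, injection_time = inj,
                   draw_times = draws, draw_barcodes = barcodes),
              class = "test_order")
  })
}

# ISO 8601 (YYYY-MM-DDTHH:MM:SS, 'T' or space separator); tz fixed UTC so
# elapsed minutes are invariant to the host timezone.
parse_iso_time <- function(x) {
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

#' Merge a quantitated batch with the test orders
#'
#' Joins the per-specimen quantitation report onto each order's draw
#' barcodes. Orphan specimens (patient rows with no matching order) and
#' unfilled orders (orders with missing draws) are reported separately;
#' nothing is silently lost. A barcode claimed by more than one order is a
#' hard error.
#'
#' @param batch An `"instrument_batch"`.
#' @param orders List of `"test_order"` objects.
#' @param quant_report The `report` data frame from [quantitate_batch()].
#' @return A list with `patients` (per patient: the order plus a
#'   `concentrations` data frame with elapsed times), `orphans` (barcodes),
#'   and `unfilled` (patient ids with their missing barcodes).
#' @export
merge_batch <- function(batch, orders, quant_report) {
  all_claimed <- unlist(lapply(orders, `[[`, "draw_barcodes"))
  if (anyDuplicated(all_claimed))
    stop("duplicate barcode across orders: ",
         paste(unique(all_claimed[duplicated(all_claimed)]), collapse = ", "))

  patients <- list()
  unfilled <- list()
  for (ord in orders) {
    idx <- match(ord$draw_barcodes, quant_report$barcode)
    if (anyNA(idx)) {
      unfilled[[ord$patient_id]] <- ord$draw_barcodes[is.na(idx)]
      conc <- data.frame(barcode = ord$draw_barcodes,
                         concentration = NA_real_,
                         flag = "missing", stringsAsFactors = FALSE)
      conc$concentration[!is.na(idx)] <-
        quant_report$concentration[idx[!is.na(idx)]]
      conc$flag[!is.na(idx)] <- quant_report$flag[idx[!is.na(idx)]]
    } else {
      conc <- data.frame(barcode = ord$draw_barcodes,
                         concentration = quant_report$concentration[idx],
                         flag = quant_report$flag[idx],
                         stringsAsFactors = FALSE)
    }
    conc$elapsed_min <- as.numeric(difftime(ord$draw_times,
                                            ord$injection_time,
                                            units = "mins"))
    patients[[ord$patient_id]] <- list(order = ord, concentrations = conc)
  }
  batch_patient <- batch$samples$barcode[batch$samples$role == "patient"]
  orphans <- setdiff(batch_patient, all_claimed)
  list(patients = patients, orphans = orphans, unfilled = unfilled)
}

#' Write the LIS-ready result file
#'
#' Emits one row per patient in a fixed column order with fixed decimal
#' formatting (GFR to one decimal, C2 to two, R-squared to four), UTF-8,
#' trailing newline: byte-identical across runs on identical input.
#' Withheld results are emitted as rows with `status = "withheld"` and a
#' machine-readable reason rather than omitted, for auditability.
#'
#' @param results List of `"clearance_result"` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_result_csv <- function(results, path) {
  fmt1 <- function(x) ifelse(is.finite(x), sprintf("%.1f", x), "")
  fmt2 <- function(x) ifelse(is.finite(x), sprintf("%.2f", x), "")
  fmt4 <- function(x) ifelse(is.finite(x), sprintf("%.4f", x), "")
  rows <- lapply(results, function(r) {
    data.frame(
      patient_id = r$patient_id,
      status = r$status,
      gfr_normalized = fmt1(r$gfr_normalized),
      gfr_bm = fmt1(r$gfr_bm),
      c2_raw = fmt2(r$c2),
      r_squared = fmt4(r$r_squared),
      kdigo = ifelse(is.na(r$kdigo), "", r$kdigo),
      reason = ifelse(is.na(r$reason), "", r$reason),
      flags = paste(r$flags, collapse = ";"),
      dose_mg = fmt2(r$dose),
      bsa_m2 = fmt2(r$bsa),
      elapsed_min = paste(fmt1(r$elapsed_min), collapse = ";"),
      software = paste0("iohexolGFR ",
                        as.character(utils::packageVersion("iohexolGFR"))),
      stringsAsFactors = FALSE)
  })
  header <- c("patient_id", "status", "gfr_normalized", "gfr_bm", "c2_raw",
              "r_squared", "kdigo", "reason", "flags", "dose_mg", "bsa_m2",
              "elapsed_min", "software")
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(character(0), ncol = length(header)),
                                  stringsAsFactors = FALSE), header)
  con <- file(path, open = "wb")  # binary: fixed \n eol on every platform
  on.exit(close(con))
  utils::write.csv(tab, con, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' Run the complete batch pipeline
#'
#' parse -> quantitate -> merge -> per-patient mGFR -> result file. The
#' returned object also carries the quantitation report and the merge
#' accounting so no input row goes unexplained.
#'
#' @param batch_csv Path to the instrument export.
#' @param orders_csv Path to the test-order table.
#' @param out_csv Optional path for the LIS result file.
#' @param config A [gfr_config()].
#' @param column_map Optional vendor column map for the instrument file.
#' @return A list with `results` (clearance results), `quant`,
#'   `merged`, and `batch`.
#' @export
#' @examples
#' \donttest{
#' study <- simulate_study(n_patients = 2, gfr = 100, seed = 1)
#' bf <- tempfile(fileext = ".csv"); of <- tempfile(fileext = ".csv")
#' write_instrument_csv(study$batch, bf)
#' write.csv(study$orders, of, row.names = FALSE)
#' run_gfr_pipeline(bf, of)$results
#' }
run_gfr_pipeline <- function(batch_csv, orders_csv, out_csv = NULL,
                             config = gfr_config(), column_map = NULL) {
  batch <- parse_instrument_csv(batch_csv, column_map = column_map)
  orders <- parse_order_csv(orders_csv, config = config)
  quant <- quantitate_batch(batch$samples[batch$samples$valid, , drop = FALSE],
                            config = config)
  merged <- merge_batch(batch, orders, quant$report)
  results <- lapply(merged$patients, function(p)
    compute_mgfr(p$order, p$concentrations, config = config))
  if (!is.null(out_csv)) write_result_csv(results, out_csv)
  list(results = results, quant = quant, merged = merged, batch = batch)
}
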