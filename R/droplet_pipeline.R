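# Droplet barcoded-sequencing count processing: UMI deduplication,
# read-count filtering, reporter-based species calling, fraction and yield
# computation per droplet.

#' Pipeline configuration
#'
#' Thresholds and constants of the droplet count-processing pipeline. The
#' per-droplet UMI thresholds are applied non-strictly (>= 10 hairpin and
#' >= 20 ribozyme UMIs by default). The per-reporter concentration used for
#' yield conversion is the nominal reporter concentration diluted from one
#' small droplet into the fused volume (`small_droplet_pL /
#' (carrier_droplet_pL + k * small_droplet_pL)` for k fused small
#' droplets, approximated by the number of retained reporters); supply
#' `effective_reporter_uM` to bypass the dilution model.
#'
#' @param reporter_map Named list mapping each hairpin reporter id to the
#'   character vector of species its fragment mixture encodes. Required
#'   for droplet calling.
#' @param min_reads_per_umi_ribozyme,min_reads_per_umi_hairpin Minimum
#'   reads for a UMI to be kept, per molecule class (default 2).
#' @param reporter_min_share Minimum share of hairpin UMIs for a reporter
#'   to be retained (default 0.075).
#' @param min_hairpin_umis,min_ribozyme_umis Minimum retained UMIs for a
#'   droplet to be kept (defaults 10 and 20).
#' @param reporter_concentration_uM Nominal reporter concentration in the
#'   small droplets (default 0.03 uM).
#' @param small_droplet_pL,carrier_droplet_pL Droplet volumes of the
#'   dilution model (defaults 5 and 50 pL).
#' @param effective_reporter_uM Optional fixed effective per-reporter
#'   concentration (uM) overriding the dilution model.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(reporter_map = NULL,
                            min_reads_per_umi_ribozyme = 2,
                            min_reads_per_umi_hairpin = 2,
                            reporter_min_share = 0.075,
                            min_hairpin_umis = 10,
                            min_ribozyme_umis = 20,
                            reporter_concentration_uM = 0.03,
                            small_droplet_pL = 5,
                            carrier_droplet_pL = 50,
                            effective_reporter_uM = NULL) {
  stopifnot(min_reads_per_umi_ribozyme >= 0, min_reads_per_umi_hairpin >= 0,
            reporter_min_share >= 0, reporter_min_share <= 1,
            min_hairpin_umis >= 0, min_ribozyme_umis >= 0,
            reporter_concentration_uM >= 0)
  structure(
    list(reporter_map = reporter_map,
         min_reads_per_umi_ribozyme = min_reads_per_umi_ribozyme,
         min_reads_per_umi_hairpin = min_reads_per_umi_hairpin,
         reporter_min_share = reporter_min_share,
         min_hairpin_umis = min_hairpin_umis,
         min_ribozyme_umis = min_ribozyme_umis,
         reporter_concentration_uM = reporter_concentration_uM,
         small_droplet_pL = small_droplet_pL,
         carrier_droplet_pL = carrier_droplet_pL,
         effective_reporter_uM = effective_reporter_uM),
    class = "pipeline_config"
  )
}

.is_hairpin <- function(molecule_id, config) {
  if (is.null(config$reporter_map)) {
    stop("pipeline_config needs a reporter_map to classify molecules")
  }
  molecule_id %in% names(config$reporter_map)
}

#' Deduplicate UMI records
#'
#' Merges records sharing the same (droplet barcode, molecule identity,
#' UMI) key, summing their read counts; total reads are conserved.
#' Malformed records (missing fields or nonpositive read counts) are
#' skipped with a log message.
#'
#' @param records Data frame with columns `droplet_barcode`,
#'   `molecule_id`, `umi`, `read_count`.
#' @return Deduplicated data frame with the same columns, one row per key.
#' @export
dedup_umis <- function(records) {
  need <- c("droplet_barcode", "molecule_id", "umi", "read_count")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  ok <- !is.na(records$droplet_barcode) & records$droplet_barcode != "" &
    !is.na(records$molecule_id) & records$molecule_id != "" &
    !is.na(records$umi) & records$umi != "" &
    !is.na(records$read_count) & records$read_count >= 1
  if (any(!ok)) {
    message("skipping ", sum(!ok), " malformed record(s)")
    records <- records[ok, , drop = FALSE]
  }
  if (nrow(records) == 0L) return(records[, need])
  key <- paste(records$droplet_barcode, records$molecule_id, records$umi,
               sep = "\r")
  counts <- rowsum(records$read_count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- records[first, need, drop = FALSE]
  out$read_count <- counts[match(key[first], rownames(counts)), 1L]
  rownames(out) <- NULL
  out
}

#' Filter UMIs by per-class read-count thresholds
#'
#' Keeps deduplicated UMI records whose read count reaches the threshold
#' of their molecule class (ribozyme or hairpin reporter), removing
#' low-count UMIs that typically arise from sequencing errors.
#'
#' @param records Deduplicated data frame from [dedup_umis()].
#' @param config A [pipeline_config()] with a `reporter_map`.
#' @return Filtered data frame.
#' @export
filter_umis <- function(records, config) {
  stopifnot(inherits(config, "pipeline_config"))
  hp <- .is_hairpin(records$molecule_id, config)
  thr <- ifelse(hp, config$min_reads_per_umi_hairpin,
                config$min_reads_per_umi_ribozyme)
  out <- records[records$read_count >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call one droplet from its filtered UMI records
#'
#' Applies the per-droplet rules: (1) retain hairpin reporters whose UMIs
#' make up at least `reporter_min_share` of all hairpin UMIs; (2) the
#' droplet's species set is the union of fragment sets encoded by retained
#' reporters; (3) ribozyme UMIs of species outside that set are discarded;
#' (4) the droplet is rejected unless retained hairpin UMIs reach
#' `min_hairpin_umis` and retained ribozyme UMIs reach
#' `min_ribozyme_umis`; (5) species fractions are per-species ribozyme
#' UMIs over total ribozyme UMIs, with zero fractions for encoded species
#' without UMIs. Yield is attached via [compute_yield()].
#'
#' @param records Filtered UMI records of a single droplet barcode.
#' @param config A [pipeline_config()] with a `reporter_map`.
#' @return Object of class `droplet_measurement` (list with
#'   `droplet_barcode`, `reporters`, `species`, `umi_counts`, `fractions`,
#'   `n_hairpin_umis`, `n_ribozyme_umis`, `yield_uM`), or a rejection:
#'   list with `droplet_barcode`, `rejected = TRUE` and `reason` in
#'   `no_reporter`, `low_hairpin`, `low_ribozyme`.
#' @export
call_droplet <- function(records, config) {
  stopifnot(inherits(config, "pipeline_config"))
  bc <- unique(records$droplet_barcode)
  if (length(bc) != 1L) stop("records must belong to a single droplet barcode")
  hp <- records[.is_hairpin(records$molecule_id, config), , drop = FALSE]
  rb <- records[!.is_hairpin(records$molecule_id, config), , drop = FALSE]
  reject <- function(reason) {
    structure(list(droplet_barcode = bc, rejected = TRUE, reason = reason),
              class = "droplet_rejection")
  }
  if (nrow(hp) == 0L) return(reject("no_reporter"))
  hp_umis <- table(hp$molecule_id)  # one row per UMI after dedup
  share <- hp_umis / sum(hp_umis)
  retained <- names(share)[share >= config$reporter_min_share]
  if (length(retained) == 0L) return(reject("no_reporter"))
  species <- sort(unique(unlist(config$reporter_map[retained])))
  rb <- rb[rb$molecule_id %in% species, , drop = FALSE]
  n_hp <- sum(hp_umis[retained])
  n_rb <- nrow(rb)
  if (n_hp < config$min_hairpin_umis) return(reject("low_hairpin"))
  if (n_rb < config$min_ribozyme_umis) return(reject("low_ribozyme"))
  umi_counts <- stats::setNames(integer(length(species)), species)
  tab <- table(rb$molecule_id)
  umi_counts[names(tab)] <- as.integer(tab)
  meas <- structure(
    list(droplet_barcode = bc, reporters = retained, species = species,
         umi_counts = umi_counts, fractions = umi_counts / n_rb,
         n_hairpin_umis = as.integer(n_hp), n_ribozyme_umis = as.integer(n_rb),
         yield_uM = NA_real_),
    class = "droplet_measurement"
  )
  meas$yield_uM <- compute_yield(meas, config)
  meas
}

#' Convert a droplet's UMI counts into a yield in uM
#'
#' The droplet-specific UMI-to-concentration conversion uses the retained
#' hairpin reporters of known concentration: conversion = (number of
#' retained reporters x effective per-reporter concentration) / total
#' retained hairpin UMIs; yield = total ribozyme UMIs x conversion.
#'
#' @param droplet A `droplet_measurement` from [call_droplet()].
#' @param config A [pipeline_config()].
#' @return Yield in uM.
#' @export
compute_yield <- function(droplet, config) {
  stopifnot(inherits(droplet, "droplet_measurement"),
            inherits(config, "pipeline_config"))
  k <- length(droplet$reporters)
  if (droplet$n_hairpin_umis <= 0L) {
    stop("undefined yield: no retained hairpin UMIs")
  }
  eff <- config$effective_reporter_uM
  if (is.null(eff)) {
    dilution <- config$small_droplet_pL /
      (config$carrier_droplet_pL + k * config$small_droplet_pL)
    eff <- config$reporter_concentration_uM * dilution
  }
  conversion <- (k * eff) / droplet$n_hairpin_umis
  droplet$n_ribozyme_umis * conversion
}

#' Run the full droplet count-processing pipeline
#'
#' Deduplicates, filters, and calls every droplet barcode, returning the
#' per-droplet compositions in the long format consumed by
#' [aggregate_networks()] together with a rejection log.
#'
#' @param records Raw UMI records (see [dedup_umis()]).
#' @param config A [pipeline_config()] with a `reporter_map`.
#' @return List of class `droplet_pipeline_result` with `droplets` (long
#'   data frame: `droplet_id`, `species`, `umi_count`, `fraction`,
#'   `yield_uM`, `n_hairpin_umis`, `n_ribozyme_umis`), `measurements`
#'   (list of `droplet_measurement`), and `rejections` (data frame
#'   `droplet_barcode`, `reason`).
#' @export
process_droplets <- function(records, config) {
  stopifnot(inherits(config, "pipeline_config"))
  deduped <- dedup_umis(records)
  filtered <- filter_umis(deduped, config)
  by_bc <- split(filtered, filtered$droplet_barcode)
  meas <- list()
  rej <- list()
  for (bc in names(by_bc)) {
    res <- call_droplet(by_bc[[bc]], config)
    if (inherits(res, "droplet_rejection")) {
      rej[[length(rej) + 1L]] <- data.frame(droplet_barcode = bc,
                                            reason = res$reason,
                                            stringsAsFactors = FALSE)
    } else {
      meas[[length(meas) + 1L]] <- res
    }
  }
  droplets <- if (length(meas) > 0L) {
    do.call(rbind, lapply(meas, function(m) {
      data.frame(droplet_id = m$droplet_barcode, species = m$species,
                 umi_count = as.integer(m$umi_counts),
                 fraction = as.vector(m$fractions),
                 yield_uM = m$yield_uM,
                 n_hairpin_umis = m$n_hairpin_umis,
                 n_ribozyme_umis = m$n_ribozyme_umis,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(droplet_id = character(), species = character(),
               umi_count = integer(), fraction = numeric(),
               yield_uM = numeric(), n_hairpin_umis = integer(),
               n_ribozyme_umis = integer(), stringsAsFactors = FALSE)
  }
  rejections <- if (length(rej) > 0L) {
    do.call(rbind, rej)
  } else {
    data.frame(droplet_barcode = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(droplets = droplets, measurements = meas,
                 rejections = rejections),
            class = "droplet_pipeline_result")
}

#' @export
print.droplet_pipeline_result <- function(x, ...) {
  cat("Droplet pipeline:", length(x$measurements), "droplet(s) retained,",
      nrow(x$rejections), "rejected\n")
  if (nrow(x$rejections) > 0L) print(table(x$rejections$reason))
  invisible(x)
}

#' Read / write UMI record tables as TSV
#'
#' Schema: `droplet_barcode`, `molecule_id`, `umi`, `read_count`,
#' tab-separated with a header.
#'
#' @param file Path to a TSV file.
#' @param records Data frame of UMI records to write.
#' @return Data frame of records ([read_umi_records()]) or `file`,
#'   invisibly.
#' @export
read_umi_records <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname read_umi_records
#' @export
write_umi_records <- function(records, file) {
  utils::write.table(records, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
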