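#' Read / write a flat key-value run configuration
#'
#' The run configuration mirrors the fields of [founder_filter_config()],
#' [density_filter_config()], [hmm_config()], [qc_config()] and (for
#' simulation) [sim_config()] as flat `key = value` lines; `#` starts a
#' comment. Unknown keys are an error, naming the field.
#'
#' @param path file path.
#' @return Named list of parsed values (numerics where possible).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3]
  if (length(bad)) stop("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  known <- c(names(formals(founder_filter_config)),
             names(formals(density_filter_config)),
             names(formals(hmm_config)), names(formals(qc_config)),
             setdiff(names(formals(sim_config)), c("genome", "filter")),
             "cm_per_mb")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  out
}

take <- function(config, builder) {
  args <- as.list(config)[intersect(names(config), names(formals(builder)))]
  do.call(builder, args)
}

# small deterministic content fingerprint (31-based polynomial hash,
# carried in doubles to stay within exact integer arithmetic)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

output_header <- function(seed, config) {
  paste0("mosaicimpute ", as.character(utils::packageVersion("mosaicimpute")),
         " seed=", seed, " config=", config_hash(config))
}

#' Simulate a dataset and write every pipeline input dialect
#'
#' @param out_dir output directory.
#' @param config named list of [sim_config()] fields (from
#'   [read_run_config()]), or `NULL` for defaults.
#' @param genome a [genome_spec()] (required).
#' @param seed RNG seed (overrides any `seed` in `config`).
#' @return The `sim_cross` object, invisibly.
#' @export
run_simulate <- function(out_dir, genome, config = NULL, seed = 1) {
  config <- config[intersect(names(config),
                             setdiff(names(formals(sim_config)),
                                     c("genome", "filter", "seed")))]
  cfg <- do.call(sim_config, c(list(genome = genome, seed = seed), config))
  sim <- simulate_cross(cfg)
  sim_write_dataset(sim, out_dir)
  writeLines(paste0("# ", output_header(seed, config)),
             file.path(out_dir, "RUNINFO"))
  invisible(sim)
}

#' Select per-family informative markers from founder genotypes
#'
#' Chains founder VCF ingestion, the MAF/AC/QUAL founder variant filter
#' and within-family informative marker selection, writing one marker
#' table per nuclear family plus a per-family count log.
#'
#' @param founder_vcf path to the founder VCF.
#' @param pedigree_tsv path to the pedigree table.
#' @param out_dir output directory.
#' @param config named list of configuration fields (or `NULL`).
#' @param seed seed recorded in output headers (selection itself is
#'   deterministic).
#' @return Named list of per-family `marker_set`s, invisibly; the count
#'   log is written to `marker_counts.tsv`.
#' @export
run_select <- function(founder_vcf, pedigree_tsv, out_dir, config = NULL,
                       seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fs <- read_founder_vcf(founder_vcf)
  fcfg <- take(config, founder_filter_config)
  fs <- filter_founder_variants(fs, fcfg)
  flog <- attr(fs, "filter_log")
  message("founder filter kept ", flog[["n_kept"]], "/",
          flog[["n_input"]], " sites (",
          flog[["n_fail_maf"]], " failed MAF, ", flog[["n_fail_ac"]],
          " failed AC, ", flog[["n_fail_qual"]], " failed QUAL)")
  ped <- load_pedigree(pedigree_tsv)
  hdr <- output_header(seed, config)
  sets <- lapply(ped$families, function(fam) {
    m <- select_family_informative(fs, fam)
    write_marker_table(m, file.path(out_dir,
                                    paste0("markers_", fam$f2, ".tsv")),
                       header_lines = hdr)
    m
  })
  counts <- data.frame(family = names(sets),
                       n_markers = vapply(sets, nrow, 0L))
  utils::write.table(counts, file.path(out_dir, "marker_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("informative markers per family: ",
          paste(counts$family, counts$n_markers, sep = "=",
                collapse = ", "))
  invisible(sets)
}

#' Impute founder mosaics for a cohort of low-coverage offspring
#'
#' Chains read-count extraction and polarization, the per-individual
#' marker-density filter, chromosome-specific HMM decoding, close
#' double-crossover removal, the call-rate / crossover-outlier filter,
#' 1-Mb binning and R/qtl export. A failure confined to one individual is
#' recorded and does not abort the batch.
#'
#' @param offspring file path of the multi-sample offspring VCF (or a
#'   depth TSV `chrom pos sample n_ref n_alt`).
#' @param marker_files named list (by F2 id) of marker-table paths or
#'   `marker_set`s.
#' @param pedigree_tsv path to the pedigree table.
#' @param genome a [genome_spec()] or path to a genome TSV.
#' @param out_dir output directory.
#' @param config named list of configuration fields (or `NULL`).
#' @param seed seed recorded in output headers.
#' @return list `seg` (post-QC `mosaic_seg` of kept individuals),
#'   `binned`, `qc` (per-individual QC table with drop reasons),
#'   invisibly. Writes `segments.tsv`, `bins_rqtl.csv`, `qc_report.tsv`,
#'   `breakpoints.tsv`.
#' @export
run_impute <- function(offspring, marker_files, pedigree_tsv, genome,
                       out_dir, config = NULL, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(genome)) genome <- read_genome_spec(genome)
  dcfg <- take(config, density_filter_config)
  hcfg <- take(config, hmm_config)
  qcfg <- take(config, qc_config)
  depths <- if (grepl("\\.vcf(\\.gz)?$", offspring)) {
    read_offspring_vcf(offspring)
  } else {
    read_depth_table(offspring)
  }
  ped <- load_pedigree(pedigree_tsv)
  f2s <- names(ped$families)
  markers <- lapply(marker_files, function(m) {
    if (inherits(m, "marker_set")) m else read_marker_table(m)
  })

  qc_rows <- list(); mosaics <- list()
  for (f2 in f2s) {
    res <- tryCatch({
      obs <- extract_depths(depths, markers[[f2]], f2)
      df <- density_filter(obs, genome, dcfg)
      if (!df$keep) {
        list(qc = data.frame(individual = f2, density = df$density,
                             call_rate = NA_real_, crossovers = NA_real_,
                             dropped = TRUE,
                             reason = "density below threshold"))
      } else {
        seg <- reconstruct_mosaic(obs, genome, hcfg, f2)
        seg <- remove_close_double_crossovers(seg, qcfg)
        cr <- call_rate(seg, genome)
        co <- unname(count_crossovers(seg))
        drop <- cr < qcfg$min_call_rate
        list(seg = if (!drop) seg,
             qc = data.frame(individual = f2, density = df$density,
                             call_rate = cr, crossovers = co,
                             dropped = drop,
                             reason = if (drop) "call rate below threshold"
                             else ""))
      }
    }, error = function(e) {
      list(qc = data.frame(individual = f2, density = NA_real_,
                           call_rate = NA_real_, crossovers = NA_real_,
                           dropped = TRUE,
                           reason = paste0("error: ", conditionMessage(e))))
    })
    qc_rows[[f2]] <- res$qc
    if (!is.null(res$seg)) mosaics[[f2]] <- res$seg
  }
  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL
  if (!length(mosaics)) stop("no individual passed quality control")
  seg <- bind_mosaics(mosaics)
  outliers <- crossover_outliers(seg, genome, qcfg)
  qc$outlier <- outliers$flagged[match(qc$individual, outliers$individual)]
  binned <- bin_genotypes(seg, genome, qcfg)

  hdr <- output_header(seed, config)
  write_segments(seg, file.path(out_dir, "segments.tsv"),
                 header_lines = hdr)
  con <- file(file.path(out_dir, "breakpoints.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(seg$breakpoints, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  export_rqtl(binned, file.path(out_dir, "bins_rqtl.csv"),
              cm_per_mb = if (!is.null(config$cm_per_mb)) config$cm_per_mb
              else hcfg$recomb_rate_cm_per_mb)
  con <- file(file.path(out_dir, "qc_report.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(qc, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  message(sum(qc$dropped), "/", nrow(qc), " individuals dropped by QC")
  invisible(list(seg = seg, binned = binned, qc = qc))
}

#' Impute founder mosaics for a cohort held in memory
#'
#' In-memory counterpart of [run_impute()]: polarizes depths per
#' individual, applies the density filter, decodes every assayed
#' chromosome, removes close double crossovers and drops individuals
#' below the call-rate threshold.
#'
#' @param depths long depth table `chrom pos sample n_ref n_alt` (e.g.
#'   `sim$depths` from [simulate_cross()]).
#' @param markers named list of `marker_set`s, one per individual id.
#' @param genome a [genome_spec()].
#' @param hmm_cfg,qc_cfg,density_cfg stage configurations.
#' @return list `seg` (post-QC `mosaic_seg` of kept individuals),
#'   `binned`, `qc` (per-individual table with drop reasons).
#' @export
impute_cohort <- function(depths, markers, genome,
                          hmm_cfg = hmm_config(), qc_cfg = qc_config(),
                          density_cfg = density_filter_config()) {
  qc_rows <- list(); mosaics <- list()
  for (id in names(markers)) {
    obs <- extract_depths(depths, markers[[id]], id)
    df <- density_filter(obs, genome, density_cfg)
    if (!df$keep) {
      qc_rows[[id]] <- data.frame(individual = id, density = df$density,
                                  call_rate = NA_real_,
                                  crossovers = NA_real_, dropped = TRUE,
                                  reason = "density below threshold")
      next
    }
    seg <- reconstruct_mosaic(obs, genome, hmm_cfg, id)
    seg <- remove_close_double_crossovers(seg, qc_cfg)
    cr <- call_rate(seg, genome)
    drop <- cr < qc_cfg$min_call_rate
    qc_rows[[id]] <- data.frame(individual = id, density = df$density,
                                call_rate = cr,
                                crossovers = unname(count_crossovers(seg)),
                                dropped = drop,
                                reason = if (drop)
                                  "call rate below threshold" else "")
    if (!drop) mosaics[[id]] <- seg
  }
  if (!length(mosaics)) stop("no individual passed quality control")
  seg <- bind_mosaics(mosaics)
  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL
  list(seg = seg, binned = bin_genotypes(seg, genome, qc_cfg), qc = qc)
}

#' Evaluate binned genotypes against a validation set
#'
#' @param binned a `binned_genotypes` table or an R/qtl csv path written
#'   by [export_rqtl()].
#' @param validation_tsv validation table path (`chrom pos individual
#'   code`).
#' @param out_dir output directory for the per-individual / per-locus
#'   report tables and a one-page text summary.
#' @param config named list (recorded in headers).
#' @param seed seed recorded in headers.
#' @return The [agreement()] result, invisibly.
#' @export
run_evaluate <- function(binned, validation_tsv, out_dir, config = NULL,
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(binned)) binned <- read_rqtl(binned)
  val <- read_validation(validation_tsv)
  res <- agreement(binned, val)
  hdr <- output_header(seed, config)
  for (piece in c("per_individual", "per_locus")) {
    con <- file(file.path(out_dir, paste0(piece, ".tsv")), "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(res[[piece]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  writeLines(c(paste0("# ", hdr),
               sprintf("individuals evaluated: %d",
                       nrow(res$per_individual)),
               sprintf("mean per-individual agreement: %.4f",
                       res$overall$mean_individual),
               sprintf("mean per-locus agreement: %.4f",
                       res$overall$mean_locus),
               sprintf("validation entries without comparable bin: %d",
                       res$n_dropped)),
             file.path(out_dir, "summary.txt"))
  invisible(res)
}
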