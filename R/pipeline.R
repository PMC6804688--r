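#' Pipeline configuration
#'
#' Bundles every stage parameter at the study defaults: depth/quality
#' masking at 10/20, 30% missingness, diversity windows of 1 kb and 100 kb,
#' a 50 kb LD window, 0.5 Mb maximum pair distance, background LD from 1000
#' replications of 1000 SNPs, gene scans at Fst > 0.80 / Fst = 1.00 and the
#' 99th diversity percentile, and a 5 kb annotation flank.
#'
#' @param filter a [filter_config()]
#' @param pi_windows diversity window sizes (bp)
#' @param ld_window LD track window (bp)
#' @param track_window general track window (bp)
#' @param ld_max_dist maximum LD pair distance (bp)
#' @param ld_max_sites_per_chrom deterministic thinning cap for the pair
#'   scan (keeps dense cohorts at desk scale)
#' @param bld_reps,bld_snps background-LD bootstrap size
#' @param fst_thresholds strict gene-scan thresholds
#' @param pi_percentile high-diversity percentile
#' @param flank annotation flank (bp)
#' @param group_by sample partition for group statistics
#' @param seed root seed for the stochastic stages
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(filter = filter_config(),
                            pi_windows = c(1000, 100000),
                            ld_window = 50000, track_window = 100000,
                            ld_max_dist = 500000,
                            ld_max_sites_per_chrom = 1500,
                            bld_reps = 1000, bld_snps = 1000,
                            fst_thresholds = 0.80, pi_percentile = 0.99,
                            flank = 5000, group_by = "subspecies",
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates filter -> summaries -> diversity / LD -> distance -> scans
#' -> annotation over one cohort and writes every output table under
#' `outdir`: `filter_report.json`, `table1_summary.tsv`, `tracks/*.tsv`
#' (including per-window pepo-minus-ovifera difference tracks),
#' `dist.nexus`, `dist.phylip`, `tree.nwk`, `gene_stats.tsv`,
#' `scan_report.json`, `effects.tsv`, `annotation_summary.json` and
#' `run_log.txt`. Deterministic given `config$seed`.
#'
#' @param x a raw [cohort()] (as read by [read_vcf()] or simulated)
#' @param genes a `gene_models` object
#' @param ref a [read_fasta()] genome
#' @param outdir output directory
#' @param config a [pipeline_config()]
#' @return list of in-memory stage results, invisibly
#' @export
run_all <- function(x, genes, ref, outdir, config = pipeline_config()) {
  dir.create(file.path(outdir, "tracks"), showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  stamp <- function(...) log <<- c(log, sprintf(...))
  chl <- chrom_lengths(ref)
  cfg_hash <- config_hash(config)
  stamp("popgenscan run_all | config_hash=%s | seed=%d", cfg_hash, config$seed)

  # --- filtering
  masked <- mask_genotypes(x, config$filter)
  fl <- filter_sites(masked, config$filter)
  coh <- fl$cohort
  stamp("filter: %d sites in, %d non-biallelic removed, %d high-missing removed, %d retained",
        fl$report$n_input, fl$report$removed_nonbiallelic,
        fl$report$removed_missing, fl$report$retained)
  jsonlite::write_json(c(fl$report, list(config_hash = cfg_hash)),
                       file.path(outdir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- per-accession summary (Table-1-style)
  acc <- accession_summary(coh)
  utils::write.table(acc, file.path(outdir, "table1_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- groups
  groups <- split(x$samples$accession, x$samples[[config$group_by]])
  groups <- groups[order(match(names(groups), x$samples[[config$group_by]]))]
  gnames <- names(groups)

  # --- density, homogeneity, gene regression
  dens <- snp_density_windows(coh, chl, config$track_window)
  write_track_table(dens$windows, file.path(outdir, "tracks", "snp_count.tsv"))
  gdens <- gene_density_windows(genes, chl, config$track_window)
  write_track_table(gdens, file.path(outdir, "tracks", "gene_count.tsv"))
  homog <- density_homogeneity_test(dens$windows)
  reg <- tryCatch(gene_snp_density_regression(dens$windows, gdens),
                  error = function(e) list(slope = NaN, r2 = NaN, p = NaN))
  stamp("density: per-kb %0.2f-%0.2f across chromosomes; gene~snp slope %.4g (r2 %.4g)",
        min(dens$chromosomes$density_per_kb),
        max(dens$chromosomes$density_per_kb), reg$slope, reg$r2)

  # --- diversity and het tracks, per group and overall
  pi_tracks <- list()
  for (w in config$pi_windows) {
    wn <- format(w, scientific = FALSE)
    pi_tracks[[paste0("all_", wn)]] <- window_pi(coh, chl, NULL, w)
    for (g in gnames)
      pi_tracks[[paste0(g, "_", wn)]] <- window_pi(coh, chl, groups[[g]], w)
  }
  for (nm in names(pi_tracks))
    write_track_table(pi_tracks[[nm]],
                      file.path(outdir, "tracks", sprintf("pi_%s.tsv", nm)))
  het <- observed_heterozygosity(coh, chl, NULL, config$track_window)
  write_track_table(het, file.path(outdir, "tracks", "het.tsv"))

  # --- LD: pairs, decay fit, windows, background
  ld <- list()
  ld_groups <- c(list(all = NULL), groups)
  for (nm in names(ld_groups)) {
    g <- ld_groups[[nm]]
    pairs <- pairwise_r2(coh, g, max_dist = config$ld_max_dist,
                         max_sites_per_chrom = config$ld_max_sites_per_chrom)
    fit <- if (nrow(pairs) >= 50) ld_decay_fit(pairs) else NULL
    bld <- background_ld(coh, g, n_reps = config$bld_reps,
                         n_snps = config$bld_snps,
                         seed = child_seed(config$seed, paste0("bld_", nm)))
    ld[[nm]] <- list(pairs = pairs, fit = fit, bld = bld)
    write_track_table(window_ld(pairs, chl, config$ld_window),
                      file.path(outdir, "tracks", sprintf("ld_%s.tsv", nm)))
    stamp("ld[%s]: %d pairs, bld %.4f%s", nm, nrow(pairs), bld$bld,
          if (!is.null(fit)) sprintf(", r2<0.4 at %s bp",
                                     format(fit$crossings["r2_below_0.4"])) else "")
  }

  # --- distance, network export, NJ tree
  dm <- distance_matrix(coh)
  write_distance_nexus(dm, file.path(outdir, "dist.nexus"))
  write_distance_phylip(dm, file.path(outdir, "dist.phylip"))
  nwk <- nj_tree(dm)
  writeLines(unclass(nwk), file.path(outdir, "tree.nwk"))
  stamp("distance: %d pairs over %d-%d loci", sum(upper.tri(dm$d)),
        min(dm$n_loci_used[upper.tri(dm$d)]), max(dm$n_loci_used[upper.tri(dm$d)]))

  # --- gene-level scans
  gstats <- gene_stats(coh, genes, groups[1:2])
  utils::write.table(gstats, file.path(outdir, "gene_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fscan <- candidate_fst_scan(gstats, config$fst_thresholds)
  hscan <- high_diversity_scan(gstats, config$pi_percentile)
  scan_report <- list(
    config_hash = cfg_hash, n_genes = nrow(gstats),
    fst = fscan, high_diversity = hscan
  )
  jsonlite::write_json(scan_report, file.path(outdir, "scan_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  stamp("scan: %d/%d genes scanned, %d above %.2f, %d fixed",
        fscan$n_scanned, nrow(gstats),
        fscan$above[[1]]$n, config$fst_thresholds[1], fscan$fixed$n)

  # --- effect annotation
  ann <- annotate_variants(coh, genes, ref, flank = config$flank,
                           group_by = config$group_by)
  utils::write.table(ann$effects, file.path(outdir, "effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  jsonlite::write_json(unclass(ann$summary),
                       file.path(outdir, "annotation_summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  sets <- gene_set_comparisons(coh, ann$effects, config$group_by)
  # HIGH/MODERATE 100 kb tracks
  for (tier in c("HIGH", "MODERATE")) {
    sel <- ann$effects$impact == tier & !duplicated(ann$effects$site_idx)
    tr <- count_track(ann$effects$chrom[sel], ann$effects$pos[sel], chl,
                      config$track_window, tolower(paste0(tier, "_ct")))
    write_track_table(tr, file.path(outdir, "tracks",
                                    sprintf("impact_%s.tsv", tolower(tier))))
  }
  stamp("annotate: %d variants, Ka/Ks %.3f, Ts/Tv %.3f",
        ann$summary$n_variants, ann$summary$ka_ks, ann$summary$ts_tv)

  # --- subspecies difference tracks (first group minus second)
  if (length(gnames) >= 2) {
    d1 <- gnames[1]; d2 <- gnames[2]
    diff_tracks <- list(
      snp_count = window_diff(
        snp_density_windows(subset_cohort(coh, samples = groups[[d1]]),
                            chl, config$track_window)$windows,
        snp_density_windows(subset_cohort(coh, samples = groups[[d2]]),
                            chl, config$track_window)$windows),
      pi = window_diff(
        pi_tracks[[paste0(d1, "_", format(config$track_window, scientific = FALSE))]],
        pi_tracks[[paste0(d2, "_", format(config$track_window, scientific = FALSE))]]),
      ld = window_diff(window_ld(ld[[d1]]$pairs, chl, config$ld_window),
                       window_ld(ld[[d2]]$pairs, chl, config$ld_window))
    )
    for (nm in names(diff_tracks))
      write_track_table(diff_tracks[[nm]],
                        file.path(outdir, "tracks",
                                  sprintf("diff_%s_%s_minus_%s.tsv", nm, d1, d2)))
  }

  writeLines(c(sprintf("R %s | popgenscan %s", getRversion(),
                       as.character(utils::packageVersion("popgenscan"))), log),
             file.path(outdir, "run_log.txt"))
  invisible(list(filter = fl, accession_summary = acc, density = dens,
                 homogeneity = homog, regression = reg, pi = pi_tracks,
                 ld = ld, distance = dm, tree = nwk, gene_stats = gstats,
                 fst_scan = fscan, high_diversity = hscan,
                 annotation = ann, gene_sets = sets, config_hash = cfg_hash))
}

# Per-window count track from positions.
count_track <- function(chrom, pos, chrom_lengths, window, stat) {
  out <- lapply(names(chrom_lengths), function(ch) {
    w <- tile_windows(chrom_lengths[[ch]], window)
    cnt <- tabulate(window_index(pos[chrom == ch], window) + 1L,
                    nbins = nrow(w))
    data.frame(chrom = ch, start = w$start, end = w$end, stat = stat,
               value = cnt, n_sites = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-window difference of two matching tracks (first minus second),
# NaN-propagating.
window_diff <- function(t1, t2) {
  key <- function(d) paste(d$chrom, d$start)
  m <- match(key(t1), key(t2))
  if (anyNA(m)) stop("window grids do not match")
  out <- t1
  out$stat <- paste0("diff_", t1$stat)
  out$value <- t1$value - t2$value[m]
  out$n_sites <- t1$n_sites + t2$n_sites[m]
  out
}

# Cheap deterministic fingerprint of a configuration (no external digest
# dependency): multiplicative congruential hash over the deparsed config.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 69069 + b) %% 2147483647
  sprintf("%08x", h)
}
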