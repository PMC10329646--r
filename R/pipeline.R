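#' Demo study configuration
#'
#' A seeded synthetic study exercising every stage: two pQTL cohorts
#' (n = 1000 each), 500 variants in LD blocks on chr12 (sentinel block
#' inside 39-41.5 Mb), chr5 (trans block) and chr2 (null block), 60
#' aptamers, a sentinel SNP affecting three aptamers, one independent
#' trans SNP affecting two further aptamers plus one shared with the
#' sentinel, and one mediating protein (theta = 0.3 liability units per
#' SD) whose gene lies in cis with the sentinel. The GWAS cohort
#' (n = 10000) is simulated independently on the same variant panel.
#'
#' @param seed integer seed.
#' @param n_per_cohort samples per pQTL cohort, default 1000.
#' @param n_gwas GWAS cohort size, default 10000.
#' @return list with \code{config} (the pQTL-side \code{\link{sim_config}}),
#'   \code{gwas_config}, \code{sentinel}, \code{trans_snp} and
#'   \code{celltype_plan}.
#' @export
demo_config <- function(seed = 1L, n_per_cohort = 1000, n_gwas = 10000) {
  block_sizes <- c(40, 40, 420)
  n_variants <- sum(block_sizes)
  # block 1: chr12 sentinel block inside 39-41.5 Mb; block 2: chr5 trans
  # block; block 3: chr2 null background
  block_chrom <- c("12", "5", "2")
  block_start <- c(40.1e6, 60e6, 20e6)

  # variant IDs are deterministic given the layout
  cfg0 <- sim_config(n_samples = c(cohortA = n_per_cohort,
                                   cohortB = n_per_cohort),
                     n_variants = n_variants, block_sizes = block_sizes,
                     within_block_rho = 0.8, block_chrom = block_chrom,
                     block_start = block_start, n_aptamers = 60,
                     seed = seed)
  g0 <- variant_table(cfg0, rep(0.3, n_variants))
  sentinel <- g0$id[20]            # middle of the chr12 block
  trans_snp <- g0$id[60]           # middle of the chr5 block

  amap <- default_aptamer_map(60)
  # mediating aptamer's gene sits in cis with the sentinel on chr12
  amap$chrom[1] <- "12"
  amap$start[1] <- 40.15e6
  amap$end[1] <- 40.25e6

  planted <- data.frame(
    variant_id = c(sentinel, sentinel, sentinel, trans_snp, trans_snp, trans_snp),
    aptamer_id = c("APT0001", "APT0002", "APT0003",
                   "APT0002", "APT0004", "APT0005"),
    beta = c(0.5, 0.4, 0.35, 0.4, 0.5, 0.45),
    stringsAsFactors = FALSE
  )
  disease <- list(
    mediation = data.frame(aptamer_id = "APT0001", theta = 0.3,
                           stringsAsFactors = FALSE),
    direct_snp_effects = NULL,
    prevalence = 0.1
  )
  config <- sim_config(
    n_samples = c(cohortA = n_per_cohort, cohortB = n_per_cohort),
    n_variants = n_variants, block_sizes = block_sizes,
    within_block_rho = 0.8, maf_range = c(0.1, 0.5),
    block_chrom = block_chrom, block_start = block_start,
    n_aptamers = 60, aptamer_map = amap, planted_effects = planted,
    covariate_effects = list(age = 0.005, sex = 0.1, array_sd = 0.05),
    noise_sd = 1, disease = disease, seed = seed
  )
  gwas_config <- config
  gwas_config$n_samples <- c(gwas = n_gwas)
  gwas_config$seed <- config$seed + 1000L

  affected_genes <- amap$gene[match(unique(planted$aptamer_id),
                                    amap$aptamer_id)]
  cell_types <- c("microglia", "astrocyte", "neuron", "oligodendrocyte",
                  "endothelial")
  celltype_plan <- data.frame(
    gene = amap$gene,
    cell_type = ifelse(amap$gene %in% affected_genes, "microglia",
                       rep_len(c(NA, "neuron", NA, "astrocyte"),
                               nrow(amap))),
    share = NA_real_, stringsAsFactors = FALSE
  )
  list(config = config, gwas_config = gwas_config, sentinel = sentinel,
       trans_snp = trans_snp, celltype_plan = celltype_plan,
       cell_types = cell_types)
}

#' Run the end-to-end synthetic proteogenomic pipeline
#'
#' Simulate, QC, scan (per cohort and pooled), meta-analyze, run the
#' sentinel discovery loop (PheWAS + conditional selection + LD pruning),
#' train PWAS weights and compute association statistics, run MR with its
#' three sensitivity configurations, differential protein levels, and
#' cell-type enrichment. Writes per-stage TSVs and a run manifest when
#' \code{outdir} is given.
#'
#' @param demo a \code{\link{demo_config}} list (or a compatible list with
#'   the same fields).
#' @param outdir optional output directory for TSVs and the manifest.
#' @param n_pcs number of genotype PCs in the covariate set, default 2
#'   (the synthetic cohorts carry no population structure; the PCs mirror
#'   the standard covariate list).
#' @param fdr_level,p_entry,r2_prune,mr_p,mr_f,cis_window pipeline
#'   thresholds.
#' @param gwas_model GWAS export scale, "linear" (liability) or "logistic".
#' @return list with every stage output (see the vignette).
#' @export
run_pipeline <- function(demo = demo_config(), outdir = NULL, n_pcs = 2,
                         fdr_level = 0.05, p_entry = 5e-8, r2_prune = 0.85,
                         mr_p = 5e-8, mr_f = 10, cis_window = 1e6,
                         gwas_model = "linear") {
  config <- demo$config
  res <- list(config = config)

  # --- simulate
  geno <- simulate_genotypes(config)
  prot <- simulate_proteins(geno, config)
  gwas_geno <- simulate_genotypes(demo$gwas_config)
  gwas <- simulate_disease_gwas(gwas_geno, demo$gwas_config,
                                model = gwas_model)
  res$genotypes <- geno; res$truth <- prot$truth; res$gwas <- gwas

  # --- QC + normalization
  qc <- qc_pipeline(prot$raw)
  proteins <- qc$proteins
  res$qc_report <- qc$report; res$proteins <- proteins

  # --- covariates: age, sex, array, leading genotype PCs
  cov <- prot$covariates
  pcs <- genotype_pcs(geno, k = n_pcs)
  covariates <- cbind(cov[, c("sample_id", "age", "sex", "array")],
                      as.data.frame(pcs[cov$sample_id, , drop = FALSE]))

  # --- per-cohort scans + meta; pooled (joint) scan with cohort covariate
  cohorts <- split(cov$sample_id, cov$cohort)
  per_cohort <- lapply(cohorts, function(ids) {
    sub <- covariates[covariates$sample_id %in% ids, , drop = FALSE]
    pqtl_scan(geno, proteins[intersect(rownames(proteins), ids), , drop = FALSE],
              covariates = sub)
  })
  meta <- meta_fixed(per_cohort)
  pooled_cov <- covariates
  pooled_cov$cohort <- cov$cohort[match(pooled_cov$sample_id, cov$sample_id)]
  pooled <- pqtl_scan(geno, proteins, covariates = pooled_cov)
  res$scan_per_cohort <- per_cohort; res$meta <- meta; res$scan <- pooled
  res$forest <- forest_consistency(per_cohort, meta)

  # --- discovery loop
  ld <- ld_matrix(geno)
  loop <- discovery_loop(demo$sentinel, pooled, ld, fdr_level = fdr_level,
                         p_entry = p_entry, r2_prune = r2_prune)
  res$ld <- ld; res$discovery <- loop

  # --- PWAS over discovered aptamers
  amap <- config$aptamer_map
  models <- list()
  pwas_rows <- list()
  for (a in loop$aptamers) {
    gene <- amap[amap$aptamer_id == a, ]
    cis_ids <- geno$variants$id[
      geno$variants$chrom == gene$chrom &
        geno$variants$pos >= gene$start - cis_window &
        geno$variants$pos <= gene$end + cis_window]
    trans_ids <- setdiff(loop$variants, cis_ids)
    snp_set <- rbind(
      if (length(cis_ids)) data.frame(variant_id = cis_ids, role = "cis"),
      if (length(trans_ids)) data.frame(variant_id = trans_ids, role = "trans"))
    if (is.null(snp_set) || nrow(snp_set) < 1) next
    y <- residualize(stats::setNames(proteins[, a], rownames(proteins)),
                     pooled_cov)
    wm <- train_weights(geno, y, snp_set, seed = config$seed)
    models[[a]] <- wm
    if (!wm$usable) next
    pw <- pwas_assoc(wm, gwas, ld_matrix(geno, wm$weights$variant_id))
    pw$aptamer_id <- a
    pwas_rows[[a]] <- pw
  }
  pwas_res <- if (length(pwas_rows)) do.call(rbind, pwas_rows) else NULL
  if (!is.null(pwas_res)) {
    pwas_res <- postprocess_loci(pwas_res, models, geno, fdr_level = fdr_level)
  }
  res$weight_models <- models; res$pwas <- pwas_res

  # --- MR per discovered aptamer, three sensitivity configurations
  mr_rows <- list()
  for (a in loop$aptamers) {
    ex <- pooled[pooled$aptamer_id == a, , drop = FALSE]
    vi <- geno$variants[match(ex$variant_id, geno$variants$id), ]
    ex$chrom <- vi$chrom; ex$pos <- vi$pos
    sel <- select_instruments(ex, gwas, ld, p_max = mr_p, f_min = mr_f)
    gene <- amap[amap$aptamer_id == a, ]
    sens <- mr_sensitivity(sel$instruments,
                           gene_region = list(chrom = gene$chrom,
                                              start = gene$start,
                                              end = gene$end),
                           cis_window = cis_window)
    sens$aptamer_id <- a
    mr_rows[[a]] <- sens
  }
  res$mr <- if (length(mr_rows)) do.call(rbind, c(mr_rows, make.row.names = FALSE)) else NULL

  # --- differential levels on the pQTL cohort (disease status from the
  # same liability model applied to the pQTL cohort's genotypes)
  pheno_gwas <- simulate_disease_gwas(geno, config, model = "linear")
  status <- attr(pheno_gwas, "case_status")
  pheno <- data.frame(sample_id = rownames(geno$dosage),
                      group = ifelse(status == 1, "case", "control"),
                      sex = cov$sex, age = cov$age, array = cov$array,
                      stringsAsFactors = FALSE)
  res$differential <- group_compare(proteins, pheno, c("control", "case"),
                                    covariates = c("age", "sex", "array"))
  res$sex_diff <- sex_difference(proteins, pheno,
                                 strata = list(all = NULL,
                                               case = "case",
                                               control = "control"))

  # --- cell-type enrichment: discovered genes vs panel background
  expr <- simulate_celltype_expression(amap$gene, demo$cell_types,
                                       demo$celltype_plan,
                                       seed = config$seed)
  calls <- assign_specificity(expr)
  target <- amap$gene[match(loop$aptamers, amap$aptamer_id)]
  res$celltype_calls <- calls
  res$celltype <- if (length(target)) {
    celltype_enrichment(target, amap$gene, calls, "microglia")
  } else NULL

  if (!is.null(outdir)) write_run_outputs(res, outdir)
  res
}

#' Load a pipeline run configuration from YAML
#'
#' Minimal YAML front end over \code{\link{demo_config}} and the
#' \code{\link{run_pipeline}} thresholds: recognized keys are \code{seed},
#' \code{n_per_cohort}, \code{n_gwas}, and a \code{thresholds} block
#' (\code{fdr_level}, \code{p_entry}, \code{r2_prune}, \code{mr_p},
#' \code{mr_f}, \code{cis_window}).
#'
#' @param path path to a YAML file.
#' @return list with \code{demo} (a \code{\link{demo_config}}) and
#'   \code{thresholds} (named list to splice into \code{run_pipeline}).
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  demo <- demo_config(seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
                      n_per_cohort = if (is.null(y$n_per_cohort)) 1000 else y$n_per_cohort,
                      n_gwas = if (is.null(y$n_gwas)) 10000 else y$n_gwas)
  thr <- y$thresholds
  allowed <- c("fdr_level", "p_entry", "r2_prune", "mr_p", "mr_f", "cis_window")
  thr <- thr[intersect(names(thr), allowed)]
  list(demo = demo, thresholds = thr)
}

write_run_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    if (!is.null(x)) utils::write.table(
      x, file.path(outdir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  tsv(res$scan, "scan_pooled.tsv")
  tsv(res$meta, "meta.tsv")
  tsv(res$forest, "forest_consistency.tsv")
  tsv(data.frame(variant_id = res$discovery$variants), "discovery_snps.tsv")
  tsv(data.frame(aptamer_id = res$discovery$aptamers), "discovery_aptamers.tsv")
  tsv(res$pwas, "pwas.tsv")
  tsv(res$mr, "mr.tsv")
  tsv(res$differential, "differential.tsv")
  tsv(res$sex_diff, "sex_difference.tsv")
  tsv(res$celltype, "celltype_enrichment.tsv")
  write_gwas_tsv(res$gwas, file.path(outdir, "gwas_summary.tsv"))
  write_truth_json(res$truth, file.path(outdir, "truth.json"))
  jsonlite::write_json(
    list(seed = res$config$seed,
         n_samples = as.list(res$config$n_samples),
         n_variants = res$config$n_variants,
         qc = list(aptamers_in = res$qc_report$aptamers_in,
                   aptamers_out = res$qc_report$aptamers_out,
                   samples_in = res$qc_report$samples_in,
                   samples_out = res$qc_report$samples_out),
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("proteopheno"))),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
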