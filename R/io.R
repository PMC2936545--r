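#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a `probe_id` column, optional
#' annotation columns (`chromosome`, `position`, `globin`, `n_mappings`),
#' and one numeric column per sample. Missing annotation columns are filled
#' permissively (autosome 1, position 0, no flags) with a warning.
#'
#' @param path File path.
#' @return An `expression_dataset` (without replicate layers).
#' @export
read_expression <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (anyDuplicated(header))
    stop("duplicate column name(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(df))
    stop("missing `probe_id` column", call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe id(s): ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "),
         call. = FALSE)
  ann_cols <- intersect(c("chromosome", "position", "globin", "n_mappings"),
                        names(df))
  sample_cols <- setdiff(names(df), c("probe_id", ann_cols))
  mat <- as.matrix(df[sample_cols])
  bad <- which(is.na(suppressWarnings(
    matrix(as.numeric(mat), nrow(mat)))) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value at probe '%s', sample '%s'",
                 df$probe_id[bad[1, 1]], sample_cols[bad[1, 2]]),
         call. = FALSE)
  storage.mode(mat) <- "double"
  rownames(mat) <- df$probe_id
  ann <- tibble::tibble(probe_id = df$probe_id)
  defaults <- list(chromosome = "1", position = 0, globin = FALSE,
                   n_mappings = 1L)
  for (col in names(defaults)) {
    if (col %in% ann_cols) ann[[col]] <- df[[col]]
    else {
      warning("annotation column '", col, "' missing; defaulting permissive",
              call. = FALSE)
      ann[[col]] <- defaults[[col]]
    }
  }
  structure(list(log2 = mat, annotation = ann, replicates = NULL),
            class = "expression_dataset")
}

#' Write an expression dataset to TSV
#'
#' @param x An `expression_dataset` or bare matrix.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  mat <- if (inherits(x, "expression_dataset")) x$log2 else as.matrix(x)
  # 17 significant digits: doubles survive the text round trip exactly
  fmt <- matrix(sprintf("%.17g", mat), nrow(mat),
                dimnames = dimnames(mat))
  df <- if (inherits(x, "expression_dataset"))
    cbind(as.data.frame(x$annotation), as.data.frame(fmt,
                                                     check.names = FALSE))
  else data.frame(probe_id = rownames(mat),
                  as.data.frame(fmt, check.names = FALSE),
                  check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF files (".vcf", parsed with vcfR) have their GT fields converted to
#' minor-allele dosage: at each site the minor allele is determined from the
#' sample allele frequencies, and dosages count copies of that allele, so
#' every column has MAF at most 0.5. Multi-allelic sites are skipped with a
#' warning. Dosage TSVs carry columns `snp_id`, `chromosome`, `position`
#' then one 0/1/2 column per sample.
#'
#' @param path File path (`.vcf` or `.tsv`).
#' @return A `genotype_dataset`.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) return(.read_vcf(path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "chromosome", "position")
  if (!all(need %in% names(df)))
    stop("dosage TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sample_cols <- setdiff(names(df), need)
  G <- t(as.matrix(df[sample_cols]))
  colnames(G) <- df$snp_id
  structure(list(dosage = G,
                 info = tibble::tibble(snp_id = df$snp_id,
                                       chromosome = as.character(df$chromosome),
                                       position = df$position)),
            class = "genotype_dataset")
}

.read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning("skipping ", sum(multi), " multi-allelic site(s)", call. = FALSE)
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  # flip so dosage counts the minor allele
  G <- t(alt_dose)
  flip <- colMeans(G, na.rm = TRUE) / 2 > 0.5
  G[, flip] <- 2L - G[, flip, drop = FALSE]
  colnames(G) <- fix[, "ID"]
  structure(list(dosage = G,
                 info = tibble::tibble(snp_id = fix[, "ID"],
                                       chromosome = as.character(fix[, "CHROM"]),
                                       position = as.numeric(fix[, "POS"]))),
            class = "genotype_dataset")
}

#' Write genotypes as a minimal VCF (GT field)
#'
#' Dosages are encoded as unphased GT against a placeholder REF/ALT pair
#' (the ALT allele is the counted, minor allele).
#'
#' @param genotypes A `genotype_dataset`.
#' @param path Output path ending in `.vcf`.
#' @export
write_vcf <- function(genotypes, path) {
  G <- genotypes$dosage
  info <- genotypes$info[match(colnames(G), genotypes$info$snp_id), ]
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(ncol(G)), function(j) {
    gt <- ifelse(is.na(G[, j]), "./.", gt_code[as.character(G[, j])])
    paste(c(info$chromosome[j], format(info$position[j], scientific = FALSE),
            info$snp_id[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write genotypes as a dosage TSV
#'
#' @param genotypes A `genotype_dataset`.
#' @param path Output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  G <- genotypes$dosage
  info <- genotypes$info[match(colnames(G), genotypes$info$snp_id), ]
  df <- cbind(data.frame(snp_id = info$snp_id, chromosome = info$chromosome,
                         position = info$position),
              as.data.frame(t(G), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the trait table
#'
#' @param path File path.
#' @param trait_names Trait columns (stored in the attribute of the result).
#' @return A tibble with the `trait_names` attribute set.
#' @export
read_traits <- function(path, trait_names = NULL) {
  df <- tibble::as_tibble(read.delim(path, check.names = FALSE,
                                     stringsAsFactors = FALSE))
  if (is.null(trait_names))
    trait_names <- setdiff(names(df), c("sample_id", "sex", "age", "HTM",
                                        "CM", "alcohol"))
  attr(df, "trait_names") <- trait_names
  df
}

#' @rdname read_traits
#' @param traits Trait tibble.
#' @export
write_traits <- function(traits, path) {
  write.table(as.data.frame(traits), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a complete simulated dataset to a directory
#'
#' Emits the expression TSV (with annotation columns), both genotype
#' encodings (VCF and dosage TSV), the trait TSV and the ground-truth JSON.
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(ds$expression, file.path(dir, "expression.tsv"))
  write_vcf(ds$genotypes, file.path(dir, "genotypes.vcf"))
  write_genotypes_tsv(ds$genotypes, file.path(dir, "genotypes.tsv"))
  write_traits(ds$traits, file.path(dir, "traits.tsv"))
  truth <- ds$truth
  jsonlite::write_json(list(
    module_assignment = as.list(truth$module_assignment),
    eqtl_map = truth$eqtl_map, anchor_map = truth$anchor_map,
    trait_loadings = truth$trait_loadings),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes the stages in study order on an in-memory dataset (typically
#' from [simulate_dataset()]): replicate QC and bead-weighted combination,
#' quantile normalization, probe filtering, genotype QC and PCA outlier
#' removal, gender-stratified trait standardization, per-trait univariate
#' association, multivariate meta-lipid association, probe selection,
#' soft-power selection, module detection and merging, module-trait
#' correlation at the extrapolated significance level, permutation-calibrated
#' cis scans and module-level eQTL tests for the lead module, and SEM edge
#' orienting of the lead module eigengene against its associated traits.
#'
#' @param data A `sim_dataset`, or a list with `expression`, `genotypes`,
#'   `traits` elements of the same shapes.
#' @param top_fraction Probe fraction carried into the network stage.
#' @param n_perm Permutations for cis calibration.
#' @param powers Candidate soft powers.
#' @param merge_height Module merge height.
#' @param min_module_size Minimum module size.
#' @param cut_height Optional constant tree-cut height passed to
#'   [detect_modules()] (default: branch-persistence rule).
#' @param orient_traits Traits to include as nodes in the orientation stage
#'   (default the two most strongly module-associated).
#' @param do_eqtl,do_orient Stage toggles.
#' @param seed Seed for the permutation stage.
#' @return A list bundle with per-stage outputs and a `manifest` (seed,
#'   parameter hash, result hash, package version).
#' @export
run_pipeline <- function(data, top_fraction = 0.10, n_perm = 10000,
                         powers = 1:20, merge_height = 0.20,
                         min_module_size = 10, cut_height = NULL,
                         orient_traits = NULL,
                         do_eqtl = TRUE, do_orient = TRUE, seed = 1L) {
  params <- list(top_fraction = top_fraction, n_perm = n_perm,
                 powers = powers, merge_height = merge_height,
                 min_module_size = min_module_size, seed = seed)
  expr_ds <- data$expression
  geno <- data$genotypes
  traits <- data$traits
  exclusions <- list()

  ## expression QC ---------------------------------------------------------
  if (!is.null(expr_ds$replicates)) {
    qc_rep <- qc_replicates(expr_ds$replicates)
    kept <- qc_rep$sample_id[qc_rep$kept]
    exclusions$replicate_qc <- setdiff(qc_rep$sample_id, kept)
    delta <- combine_replicates(expr_ds$replicates$S1[, kept, drop = FALSE],
                                expr_ds$replicates$S2[, kept, drop = FALSE],
                                expr_ds$replicates$b1[, kept, drop = FALSE],
                                expr_ds$replicates$b2[, kept, drop = FALSE])
    expr <- quantile_normalize(log2(delta))
  } else {
    qc_rep <- NULL
    expr <- quantile_normalize(expr_ds$log2)
  }
  keep_probe <- filter_probes(expr_ds$annotation)
  exclusions$probe_filter <- expr_ds$annotation$probe_id[!keep_probe]
  expr <- expr[keep_probe, , drop = FALSE]
  ann <- expr_ds$annotation[keep_probe, ]

  ## genotype QC -----------------------------------------------------------
  gqc <- qc_genotypes(geno)
  pca <- pca_outliers(gqc$genotypes)
  exclusions$pca_outliers <- pca$outliers

  samples <- Reduce(intersect, list(colnames(expr),
                                    rownames(gqc$genotypes$dosage),
                                    traits$sample_id))
  samples <- setdiff(samples, pca$outliers)
  expr <- expr[, samples, drop = FALSE]
  G <- structure(list(dosage = gqc$genotypes$dosage[samples, , drop = FALSE],
                      info = gqc$genotypes$info), class = "genotype_dataset")
  traits <- traits[match(samples, traits$sample_id), ]

  ## traits ----------------------------------------------------------------
  traits <- standardize_traits(traits)
  trait_names <- attr(traits, "trait_names")
  Z <- as.matrix(traits[paste0("z_", trait_names)])
  colnames(Z) <- trait_names

  ## association -----------------------------------------------------------
  covars <- tibble::tibble(age = traits$age, HTM = traits$HTM,
                           CM = traits$CM, alcohol = traits$alcohol)
  meta <- purrr::map_dfr(rownames(expr), function(pr) {
    w <- fit_meta_lipids(Z, expr[pr, ], covariates = covars)
    tibble::tibble(probe_id = pr, wilks_lambda = w$lambda,
                   p_value = w$p_value)
  })

  ## network ---------------------------------------------------------------
  selected <- select_probes_by_meta_trait(meta, top_fraction)
  cmat <- cor(t(expr[selected, , drop = FALSE]))
  sp <- select_soft_power(cmat, powers = powers)
  adj <- adjacency_matrix(cmat, sp$power)
  modules <- detect_modules(adj, min_module_size = min_module_size,
                            cut_height = cut_height)
  modules <- merge_modules(modules, expr[selected, , drop = FALSE],
                           merge_height = merge_height)
  n_mod <- max(modules$assignment)
  ext <- if (n_mod > 0)
    extrapolate_module_alpha(n_mod, length(selected), sum(keep_probe))
  else list(estimated_modules = 0, alpha_adjusted = 0.05)
  mt <- if (n_mod > 0)
    module_trait_correlation(modules$eigengenes, as.data.frame(Z),
                             alpha_adj = ext$alpha_adjusted)
  else NULL

  ## lead module: strongest module-trait association ------------------------
  lead <- if (!is.null(mt) && nrow(mt))
    as.integer(sub("ME", "", mt$module[which.min(mt$p_value)])) else NA
  eqtl <- NULL
  if (do_eqtl && !is.na(lead)) {
    lead_probes <- names(modules$assignment)[modules$assignment == lead]
    pos <- ann[match(lead_probes, ann$probe_id), ]
    eqtl_cis <- purrr::map_dfr(seq_along(lead_probes), function(i) {
      pc <- permutation_calibrate(expr[lead_probes[i], ], G,
                                  pos$chromosome[i], pos$position[i],
                                  n_perm = n_perm, seed = seed + i)
      tibble::tibble(probe_id = lead_probes[i],
                     empirical_p = pc$empirical_p,
                     observed_min_p = pc$observed_min_p, pass = pc$pass)
    })
    eqtl_trans <- purrr::map_dfr(seq_along(lead_probes), function(i) {
      ts <- trans_scan(expr[lead_probes[i], ], G, pos$chromosome[i],
                       pos$position[i])
      ts$probe_id <- lead_probes[i]
      ts[ts$significant, , drop = FALSE]
    })
    eqtl <- list(cis = eqtl_cis, trans = eqtl_trans)
  }

  orient <- NULL
  if (do_orient && !is.na(lead)) {
    me <- modules$eigengenes[paste0("ME", lead), ]
    if (is.null(orient_traits)) {
      mtl <- mt[mt$module == paste0("ME", lead), ]
      orient_traits <- mtl$trait[order(mtl$p_value)][1:2]
    }
    nodes <- as.data.frame(Z[, orient_traits, drop = FALSE])
    nodes$module <- me
    # greedy anchors, one distinct SNP per node (strongest node wins ties)
    anc <- anchor_autoselect(nodes, G$dosage, method = "greedy")
    taken <- character()
    for (i in order(anc$p_value)) {
      pool <- setdiff(colnames(G$dosage), taken)
      sel <- anchor_autoselect(nodes[anc$node[i]],
                               G$dosage[, pool, drop = FALSE],
                               method = "greedy")
      anc$snp_id[i] <- sel$snp_id
      anc$p_value[i] <- sel$p_value
      taken <- c(taken, sel$snp_id)
    }
    anchors <- setNames(
      lapply(anc$snp_id, function(s) G$dosage[, s]), anc$node)
    orient <- list(anchors = anc,
                   edges = orient_network(nodes, anchors))
  }

  results <- list(
    qc_replicates = qc_rep, exclusions = exclusions,
    genotype_qc = gqc$snp_report, pca = pca$components,
    expression = expr, genotypes = G, traits = traits,
    meta_association = meta, selected_probes = selected,
    soft_power = sp$power, power_table = sp$fit_table,
    modules = modules, module_alpha = ext, module_trait = mt,
    lead_module = lead, eqtl = eqtl, orientation = orient)
  results$manifest <- list(
    seed = seed, param_hash = rlang::hash(params),
    result_hash = rlang::hash(list(results$meta_association,
                                   results$modules$assignment,
                                   results$module_trait,
                                   results$eqtl, results$orientation$edges)),
    llnet_version = as.character(utils::packageVersion("llnet")))
  results
}
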