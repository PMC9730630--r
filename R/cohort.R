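#' Simulate a paired tumor/normal DNA+RNA cohort with known ground truth
#'
#' Plants A-to-I editing sites, germline SNPs and somatic SNVs in the gene
#' territory of a (generated or supplied) reference bundle, then draws
#' per-site base-count tables for every sample, material (DNA/RNA) and
#' tissue (tumor/normal), plus an FPKM-like expression table for the ADAR
#' genes. The three planted site classes are disjoint by position.
#'
#' The noise model: per-site depth is Poisson; at a planted RNA edit the
#' alternate-read count is Binomial(depth, true level); DNA at edit sites
#' is homozygous reference; SNP carriers show their allele dosage in both
#' materials and tissues; somatic SNVs appear in tumor DNA and RNA only;
#' every remaining read misreads with probability `seq_error_rate`,
#' uniformly over the three other bases. Read strands are 50/50 except for
#' alternate reads at edit sites, whose forward probability is
#' `alt_fwd_prob` (set near 0 or 1 to inject a strand-bias artifact).
#'
#' Edits in minus-strand genes are planted as T>C on the reference-forward
#' orientation (an A>G change on the transcribed strand), so downstream
#' strand-collapse logic is genuinely exercised.
#'
#' @param config A [cohort_config()] with `seed` set (missing seed is an
#'   error: the generator refuses unseeded runs).
#' @param ref Optional [generate_reference()] bundle; generated from
#'   `config` when omitted.
#' @param alt_fwd_prob Forward-strand probability for edit-supporting
#'   reads (default 0.5, i.e. no artifact).
#' @return A list of class `synthetic_cohort`:
#'   \describe{
#'     \item{counts}{base-count tibble: `chrom, pos, ref, sample, material,
#'       tissue, A_fwd..T_fwd, A_rev..T_rev, meanQ_A..meanQ_T`.}
#'     \item{expression}{tibble `gene, sample, tissue, fpkm`.}
#'     \item{truth}{list with `edits`, `edit_levels`, `snps`, `somatic`,
#'       `expression` ground-truth tibbles.}
#'     \item{db_sites}{known-editing catalogue tibble `chrom, pos, strand`.}
#'     \item{ref}{the reference bundle, with conservation scores appended
#'       for every planted edit site.}
#'   }
#' @export
#' @examples
#' cfg <- cohort_config(
#'   genome_length = 30000, n_genes = 8, n_edit_sites = 10, n_snps = 20,
#'   n_somatic = 4, n_background = 50, seed = 7
#' )
#' cohort <- simulate_cohort(cfg)
#' head(cohort$counts)
simulate_cohort <- function(config, ref = NULL, alt_fwd_prob = 0.5) {
  stopifnot(inherits(config, "cohort_config"))
  require_seed(config)
  if (is.null(ref)) ref <- generate_reference(config)
  # offset the stream so cohort draws do not replay the reference draws
  local_seed((config$seed %% 1073741789L) + 101L)

  ref_chars <- strsplit(ref$reference, "", fixed = TRUE)[[1]]
  patients <- sprintf("P%02d", seq_len(config$n_patients))

  expression <- simulate_expression(config, patients)
  tum_p110 <- expression |>
    filter(.data$gene == "ADAR1-p110", .data$tissue == "tumor") |>
    arrange(.data$sample)
  z <- log(tum_p110$fpkm)
  z <- if (length(z) > 1 && sd(z) > 0) as.numeric(scale(z)) else rep(0, length(z))
  names(z) <- tum_p110$sample

  edits <- plant_edit_sites(config, ref, ref_chars)
  snp_taken <- ref$snps$pos

  # carriers and true editing levels per site
  kvals <- as.integer(names(config$recurrence_profile))
  k <- kvals[sample.int(length(kvals), nrow(edits), replace = TRUE,
                        prob = config$recurrence_profile)]
  k <- pmin(pmax(k, 1L), config$n_patients)
  edits$recurrence_true <- k
  edits$db_known <- runif(nrow(edits)) <
    ifelse(k >= 2, config$db_rate_recurrent, config$db_rate_singleton)

  carrier_tbl <- tibble(
    site_id = rep(edits$site_id, k),
    patient = unlist(map(k, function(m) sample(patients, m)))
  )
  an <- config$edit_level_normal
  at <- config$edit_level_tumor
  nc <- nrow(carrier_tbl)
  edit_levels <- carrier_tbl |>
    mutate(
      normal = rbeta(nc, an[1], an[2]),
      tumor = clamp01(
        rbeta(nc, at[1], at[2]) + config$adar_coupling * z[.data$patient]
      )
    ) |>
    pivot_longer(c("normal", "tumor"), names_to = "tissue", values_to = "level") |>
    left_join(select(edits, "site_id", "chrom", "pos"), by = "site_id") |>
    select("site_id", "chrom", "pos", "patient", "tissue", "level")

  # germline SNP genotypes under Hardy-Weinberg from catalogue MAFs
  snps <- ref$snps
  geno <- expand_grid(idx = seq_len(nrow(snps)), patient = patients) |>
    mutate(dosage = rbinom(n(), 2L, snps$maf[.data$idx])) |>
    filter(.data$dosage > 0) |>
    mutate(
      chrom = snps$chrom[.data$idx], pos = snps$pos[.data$idx],
      ref = snps$ref[.data$idx], alt = snps$alt[.data$idx],
      maf = snps$maf[.data$idx]
    ) |>
    select("chrom", "pos", "ref", "alt", "maf", "patient", "dosage")

  # somatic SNVs: one patient each, tumor-only, both materials
  gene_pos <- unlist(map2(ref$genes$start + 1L, ref$genes$end, seq.int))
  som_pool <- setdiff(gene_pos, c(edits$pos, snp_taken))
  som_pos <- sample(som_pool, min(config$n_somatic, length(som_pool)))
  somatic <- tibble(
    chrom = "chr1", pos = as.integer(som_pos),
    ref = ref_chars[som_pos],
    alt = map_chr(ref_chars[som_pos], function(r) sample(setdiff(BASES, r), 1)),
    patient = sample(patients, length(som_pos), replace = TRUE),
    vaf = runif(length(som_pos), 0.1, 0.6)
  )

  # background positions: error-only noise fodder
  bg_pool <- setdiff(som_pool, som_pos)
  bg_pos <- sort(sample(bg_pool, min(config$n_background, length(bg_pool))))

  counts <- draw_base_counts(
    config, ref_chars, patients, edits, edit_levels, snps, geno, somatic,
    bg_pos, alt_fwd_prob
  )

  # conservation scores for planted sites (bundle covers them from now on)
  ref$conservation <- bind_rows(
    ref$conservation,
    tibble(chrom = "chr1", pos = edits$pos, score = rnorm(nrow(edits), 1.2, 0.8))
  ) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$pos)

  db_sites <- edits |>
    filter(.data$db_known) |>
    select("chrom", "pos", "strand")

  structure(
    list(
      counts = counts,
      expression = expression,
      truth = list(
        edits = edits, edit_levels = edit_levels, snps = geno,
        somatic = somatic, expression = expression
      ),
      db_sites = db_sites,
      ref = ref
    ),
    class = "synthetic_cohort"
  )
}

# ADAR1-p110 ~22 FPKM in normal, x1.8 in tumor; ADAR2 ~2 FPKM in both;
# lognormal spread 0.15 on all values
simulate_expression <- function(config, patients) {
  base <- c("ADAR1-p110" = 22, "ADAR1-p150" = 8, "ADAR2" = 2, "GAPDH" = 400)
  fold <- c("ADAR1-p110" = 1.8, "ADAR1-p150" = 1.1, "ADAR2" = 1.0, "GAPDH" = 1.0)
  grid <- expand_grid(
    gene = names(base), sample = patients, tissue = c("normal", "tumor")
  )
  grid |>
    mutate(
      fpkm = base[.data$gene] *
        ifelse(.data$tissue == "tumor", fold[.data$gene], 1) *
        exp(rnorm(n(), 0, 0.15))
    )
}

# choose edit positions: adenosines on the transcribed strand, inside CDS
# (or UTR for a small fraction), outside simple repeats, away from contig
# ends, disjoint from the SNP catalogue, with the configured 5' C/T bias
plant_edit_sites <- function(config, ref, ref_chars) {
  margin <- 12L
  genes <- ref$genes
  pool <- pmap(
    list(genes$gene_id, genes$start, genes$end, genes$strand,
         genes$cds_start, genes$cds_end),
    function(gene_id, start, end, strand, cds_start, cds_end) {
      pos <- (start + 1L):end
      tibble(
        gene_id = gene_id, strand = strand, pos = pos,
        region = ifelse(pos > cds_start & pos <= cds_end, "CDS", "UTR")
      )
    }
  ) |>
    bind_rows() |>
    filter(
      .data$pos > margin, .data$pos <= length(ref_chars) - margin,
      ref_chars[.data$pos] == ifelse(.data$strand == "+", "A", "T")
    )
  pool <- pool[!point_in_intervals("chr1", pool$pos, ref$repeats), ]
  pool <- filter(pool, !.data$pos %in% ref$snps$pos)

  # 5' neighbor on the transcribed strand
  nb <- ifelse(
    pool$strand == "+",
    ref_chars[pool$pos - 1L],
    complement_base(ref_chars[pool$pos + 1L])
  )
  pool$ct5 <- nb %in% c("C", "T")

  pick <- function(df, n, bias) {
    if (n <= 0 || nrow(df) == 0) return(df[0, ])
    n <- min(n, nrow(df))
    n_ct <- sum(df$ct5)
    w <- rep(1, nrow(df))
    if (n_ct > 0 && n_ct < nrow(df)) {
      w[df$ct5] <- bias / n_ct
      w[!df$ct5] <- (1 - bias) / (nrow(df) - n_ct)
    }
    df[sample.int(nrow(df), n, prob = w), ]
  }
  n_utr <- round(config$utr_edit_fraction * config$n_edit_sites)
  chosen <- bind_rows(
    pick(filter(pool, .data$region == "CDS"),
         config$n_edit_sites - n_utr, config$neighbor_ct_bias),
    pick(filter(pool, .data$region == "UTR"), n_utr, config$neighbor_ct_bias)
  ) |>
    arrange(.data$pos)

  alu_flag <- point_in_intervals("chr1", chosen$pos, ref$alu)
  tibble(
    site_id = sprintf("ed%04d", seq_len(nrow(chosen))),
    chrom = "chr1",
    pos = as.integer(chosen$pos),
    ref = ifelse(chosen$strand == "+", "A", "T"),
    alt = ifelse(chosen$strand == "+", "G", "C"),
    gene_id = chosen$gene_id,
    strand = chosen$strand,
    region = chosen$region,
    is_alu = alu_flag
  )
}

draw_base_counts <- function(config, ref_chars, patients, edits, edit_levels,
                             snps, geno, somatic, bg_pos, alt_fwd_prob) {
  records <- bind_rows(
    tibble(kind = "edit", site_id = edits$site_id, pos = edits$pos,
           ref = edits$ref, alt = edits$alt),
    tibble(kind = "snp", site_id = NA_character_, pos = snps$pos,
           ref = snps$ref, alt = snps$alt),
    tibble(kind = "somatic", site_id = NA_character_, pos = somatic$pos,
           ref = somatic$ref, alt = somatic$alt),
    tibble(kind = "bg", site_id = NA_character_, pos = as.integer(bg_pos),
           ref = ref_chars[bg_pos], alt = NA_character_)
  )

  grid <- expand_grid(
    records,
    sample = patients,
    material = c("DNA", "RNA"),
    tissue = c("normal", "tumor")
  )

  grid <- grid |>
    left_join(
      select(edit_levels, "site_id", "patient", "tissue", "level"),
      by = c("site_id", sample = "patient", "tissue")
    ) |>
    left_join(
      select(geno, "pos", "patient", "dosage"),
      by = c("pos", sample = "patient")
    ) |>
    left_join(
      select(somatic, "pos", "patient", "vaf"),
      by = c("pos", sample = "patient")
    ) |>
    mutate(
      f_alt = case_when(
        .data$kind == "edit" & .data$material == "RNA" & !is.na(.data$level) ~
          .data$level,
        .data$kind == "snp" & !is.na(.data$dosage) ~ .data$dosage / 2,
        .data$kind == "somatic" & .data$tissue == "tumor" & !is.na(.data$vaf) ~
          .data$vaf,
        TRUE ~ 0
      )
    )

  n <- nrow(grid)
  depth <- rpois(n, ifelse(grid$material == "DNA",
                           config$depth_mean_dna, config$depth_mean_rna))
  alt_n <- rbinom(n, depth, grid$f_alt)
  rem <- depth - alt_n
  err_n <- rbinom(n, rem, config$seq_error_rate)
  ref_n <- rem - err_n
  e1 <- rbinom(n, err_n, 1 / 3)
  e2 <- rbinom(n, err_n - e1, 1 / 2)
  e3 <- err_n - e1 - e2

  ref_idx <- match(grid$ref, BASES)
  alt_idx <- match(grid$alt, BASES) # NA for background rows
  others_tab <- t(vapply(1:4, function(i) setdiff(1:4, i), integer(3)))
  o1 <- others_tab[ref_idx, 1]
  o2 <- others_tab[ref_idx, 2]
  o3 <- others_tab[ref_idx, 3]

  fwd <- matrix(0L, n, 4)
  rev <- matrix(0L, n, 4)
  add_split <- function(col_idx, count, p_fwd) {
    f <- rbinom(n, count, p_fwd)
    ij <- cbind(seq_len(n), col_idx)
    fwd[ij] <<- fwd[ij] + f
    rev[ij] <<- rev[ij] + (count - f)
    invisible(NULL)
  }
  add_split(ref_idx, ref_n, 0.5)
  alt_col <- ifelse(is.na(alt_idx), 1L, alt_idx) # dummy col, count 0 when NA
  add_split(alt_col, ifelse(is.na(alt_idx), 0L, alt_n),
            ifelse(grid$kind == "edit", alt_fwd_prob, 0.5))
  add_split(o1, e1, 0.5)
  add_split(o2, e2, 0.5)
  add_split(o3, e3, 0.5)

  tot <- fwd + rev
  qual <- matrix(NA_real_, n, 4)
  has <- tot > 0
  qual[has] <- round(draw_baseq(sum(has)), 1)

  out <- tibble(
    chrom = "chr1",
    pos = grid$pos,
    ref = grid$ref,
    sample = grid$sample,
    material = grid$material,
    tissue = grid$tissue
  )
  for (j in 1:4) out[[paste0(BASES[j], "_fwd")]] <- fwd[, j]
  for (j in 1:4) out[[paste0(BASES[j], "_rev")]] <- rev[, j]
  for (j in 1:4) out[[paste0("meanQ_", BASES[j])]] <- qual[, j]
  arrange(out, .data$pos, .data$sample, .data$material, .data$tissue)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf(
    "  %d patients; %s base-count rows; %d planted edits, %d SNP genotypes, %d somatic\n",
    x$ref$config$n_patients, format(nrow(x$counts), big.mark = ","),
    nrow(x$truth$edits), nrow(x$truth$snps), nrow(x$truth$somatic)
  ))
  invisible(x)
}
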