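#' Construct a genotype matrix
#'
#' A `genotype_matrix` stores minor-allele dosages (0, 1, 2 or `NA`) for a
#' set of persons at a set of named SNPs.  Rows are persons, columns SNPs.
#'
#' @param dosages numeric matrix of dosages in \{0, 1, 2, NA\}, persons in
#'   rows, SNPs in columns.
#' @param person_ids character vector of unique person identifiers, aligned
#'   to rows.  Defaults to `rownames(dosages)`.
#' @param snp_ids character vector of unique SNP identifiers, aligned to
#'   columns.  Defaults to `colnames(dosages)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (integer matrix with dimnames), `person_ids`, `snp_ids`.
#' @export
genotype_matrix <- function(dosages, person_ids = rownames(dosages),
                            snp_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(person_ids)) person_ids <- paste0("p", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  person_ids <- as.character(person_ids)
  snp_ids <- as.character(snp_ids)
  if (length(person_ids) != nrow(dosages))
    stop("person_ids must align one-to-one with rows of dosages")
  if (length(snp_ids) != ncol(dosages))
    stop("snp_ids must align one-to-one with columns of dosages")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (anyDuplicated(person_ids)) stop("person_ids must be unique")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("dosage %s at position %d is not in {0, 1, 2, NA}",
                 format(dosages[bad]), bad))
  }
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(person_ids, snp_ids)
  structure(list(dosages = dosages, person_ids = person_ids,
                 snp_ids = snp_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d persons x %d SNPs\n",
              length(x$person_ids), length(x$snp_ids)))
  cat("SNPs:", paste(x$snp_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

check_dosages <- function(g) {
  if (!is.numeric(g)) stop("dosages must be numeric")
  bad <- !(g %in% c(0, 1, 2)) & !is.na(g)
  if (any(bad))
    stop(sprintf("invalid dosage value(s): %s",
                 paste(unique(g[bad]), collapse = ", ")))
  g
}

#' Minor allele frequency of a dosage vector
#'
#' Computes the allele frequency of the counted allele from minor-allele
#' dosages, using non-missing calls only.  The counted allele must be the
#' minor allele: a frequency above 0.5 signals a coding error and raises
#' an error rather than silently re-orienting.
#'
#' @param g numeric vector of dosages in \{0, 1, 2, NA\}.
#' @return The allele frequency, a proportion in \[0, 0.5\].
#' @examples
#' minor_allele_freq(c(0, 1, 1, 2))  # 0.5
#' @export
minor_allele_freq <- function(g) {
  check_dosages(g)
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("no calls: all dosages are missing")
  maf <- sum(g) / (2 * length(g))
  if (maf > 0.5)
    stop(sprintf(
      "dosage not minor-allele coded: counted-allele frequency %.4f > 0.5",
      maf))
  maf
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test of genotype counts against Hardy-Weinberg
#' proportions, conditional on the observed allele counts.  The p-value
#' sums, over every heterozygote count consistent with the allele counts,
#' the conditional probabilities not exceeding that of the observed
#' configuration (no mid-p correction).  Probabilities are evaluated by the
#' standard two-term recurrence over heterozygote counts.
#'
#' @param counts integer vector of length 3: counts of (major homozygotes,
#'   heterozygotes, minor homozygotes).  Orientation is resolved
#'   internally, so the reversed order gives the same p-value.
#' @return The exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(c(25, 50, 25))
#' @export
hwe_exact_test <- function(counts) {
  if (length(counts) != 3L) stop("counts must be a triple (hom, het, hom)")
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  counts <- as.integer(round(counts))
  n <- sum(counts)
  if (n < 1L) stop("need at least one genotyped individual")
  n_het <- counts[2L]
  rare <- 2L * min(counts[1L], counts[3L]) + n_het  # rare-allele copies
  if (rare == 0L) return(1.0)                       # monomorphic
  h_max <- if (rare %% 2L == 0L) min(rare, 2L * n - rare) else
    min(rare, 2L * n - rare)
  hs <- seq.int(rare %% 2L, h_max, by = 2L)
  # unnormalized probabilities via recurrence, anchored at the largest
  # heterozygote count to keep ratios finite
  lp <- numeric(length(hs))
  for (i in seq_along(hs)[-1L]) {
    h <- hs[i - 1L]
    hom_r <- (rare - h) / 2          # rare homozygotes at het count h
    hom_c <- n - h - hom_r
    # P(h+2)/P(h) = 4 hom_r hom_c / ((h+1)(h+2))
    lp[i] <- lp[i - 1L] + log(4 * hom_r * hom_c) -
      log((h + 1) * (h + 2))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Linkage disequilibrium between two SNPs as squared dosage correlation
#'
#' Composite genotypic r-squared: the squared Pearson correlation of the
#' two dosage vectors over pairwise-complete observations.  Under
#' Hardy-Weinberg equilibrium this is nearly identical to the haplotype
#' (EM) r-squared, and is deterministic.
#'
#' @param g1,g2 numeric dosage vectors of equal length.
#' @return r-squared, a value in \[0, 1\].
#' @export
ld_r2 <- function(g1, g2) {
  check_dosages(g1); check_dosages(g2)
  if (length(g1) != length(g2)) stop("dosage vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  g1 <- g1[ok]; g2 <- g2[ok]
  if (stats::var(g1) == 0 || stats::var(g2) == 0)
    stop("undefined r2: monomorphic input on complete pairs")
  stats::cor(g1, g2)^2
}

#' Pairwise LD matrix for a genotype matrix
#'
#' @param gm a [genotype_matrix].
#' @param persons optional character vector of person ids to restrict to
#'   (e.g. an unrelated subset chosen by the caller).
#' @return An object of class `ld_matrix`: list with `snp_ids` and `r2`
#'   (symmetric matrix with unit diagonal).
#' @export
ld_matrix <- function(gm, persons = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  if (!is.null(persons)) {
    missing_ids <- setdiff(persons, gm$person_ids)
    if (length(missing_ids))
      stop("unknown person ids: ", paste(missing_ids, collapse = ", "))
    d <- d[persons, , drop = FALSE]
  }
  m <- ncol(d)
  r2 <- diag(1, m)
  dimnames(r2) <- list(gm$snp_ids, gm$snp_ids)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        r2[i, j] <- r2[j, i] <- ld_r2(d[, i], d[, j])
      }
    }
  }
  structure(list(snp_ids = gm$snp_ids, r2 = r2), class = "ld_matrix")
}

#' Partition SNPs into tag sets by LD
#'
#' Groups SNPs into the connected components of the graph whose edges join
#' pairs with r-squared at or above `threshold`.  SNPs in different sets
#' then have below-threshold LD, the criterion used to call sets
#' independent.  Output order is deterministic: members sorted within each
#' set, sets sorted lexicographically by first member.
#'
#' @param ld an `ld_matrix` (from [ld_matrix]) or a symmetric r-squared
#'   matrix with SNP ids as dimnames.
#' @param threshold r-squared threshold in (0, 1); default 0.25.
#' @return A list of character vectors, one per set, forming a partition
#'   of the SNP ids.
#' @export
select_tag_sets <- function(ld, threshold = 0.25) {
  if (inherits(ld, "ld_matrix")) {
    r2 <- ld$r2
    ids <- ld$snp_ids
  } else {
    r2 <- as.matrix(ld)
    ids <- rownames(r2)
    if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(r2)))
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single value in (0, 1)")
  m <- length(ids)
  adj <- r2 >= threshold
  diag(adj) <- TRUE
  comp <- integer(m)            # 0 = unassigned
  k <- 0L
  for (s in seq_len(m)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  sets <- lapply(split(ids, comp), sort)
  names(sets) <- NULL
  sets[order(vapply(sets, `[`, "", 1L))]
}

#' Recoding of genotype dosages
#'
#' Additive coding is the identity on \{0, 1, 2\}; carrier coding collapses
#' heterozygotes and minor homozygotes into a single carrier class (1)
#' versus major homozygotes (0).  Missing values propagate.
#'
#' @param g numeric dosage vector.
#' @param scheme `"additive"` or `"carrier"`.
#' @return Integer vector of coded genotypes.
#' @examples
#' code_genotype(c(0, 1, 2, NA), "carrier")  # 0 1 1 NA
#' @export
code_genotype <- function(g, scheme = c("additive", "carrier")) {
  scheme <- match.arg(scheme)
  check_dosages(g)
  switch(scheme,
         additive = as.integer(g),
         carrier  = as.integer(g >= 1))
}

#' Per-SNP quality-control report
#'
#' Computes, for each SNP, the call rate, genotype counts, minor allele
#' frequency, and the exact Hardy-Weinberg p-value, plus pass flags at
#' the conventional filters (MAF >= `maf_min`, HWE p > `hwe_min`).  Flags
#' are advisory: no SNP is dropped here.
#'
#' @param gm a [genotype_matrix].
#' @param maf_min MAF filter threshold (default 0.05).
#' @param hwe_min HWE exact-test p-value threshold (default 0.01).
#' @return data.frame with one row per SNP: `snp_id`, `n`, `n_hom_major`,
#'   `n_het`, `n_hom_minor`, `call_rate`, `maf`, `hwe_p`, `maf_pass`,
#'   `hwe_pass`.
#' @export
snp_qc <- function(gm, maf_min = 0.05, hwe_min = 0.01) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- lapply(gm$snp_ids, function(s) {
    g <- gm$dosages[, s]
    gg <- g[!is.na(g)]
    n <- length(gg)
    counts <- c(sum(gg == 0L), sum(gg == 1L), sum(gg == 2L))
    maf <- if (n) minor_allele_freq(gg) else NA_real_
    data.frame(snp_id = s, n = n,
               n_hom_major = counts[1L], n_het = counts[2L],
               n_hom_minor = counts[3L],
               call_rate = n / length(g),
               maf = maf,
               hwe_p = if (n) hwe_exact_test(counts) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$maf_pass <- out$maf >= maf_min
  out$hwe_pass <- out$hwe_p > hwe_min
  out
}

#' Write a SNP QC report as TSV
#'
#' Appends the tag-set id of each SNP (from [select_tag_sets]) and writes
#' a tab-separated report with columns `snp_id`, `n`, `maf`, `hwe_p`,
#' `call_rate`, `set_id`.
#'
#' @param qc data.frame from [snp_qc].
#' @param path output file path.
#' @param tag_sets optional list of SNP-id sets from [select_tag_sets];
#'   if `NULL` every SNP gets set_id `NA`.
#' @return The written data.frame, invisibly.
#' @export
write_qc_report <- function(qc, path, tag_sets = NULL) {
  set_id <- rep(NA_integer_, nrow(qc))
  if (!is.null(tag_sets)) {
    for (k in seq_along(tag_sets))
      set_id[qc$snp_id %in% tag_sets[[k]]] <- k
  }
  out <- data.frame(snp_id = qc$snp_id, n = qc$n, maf = qc$maf,
                    hwe_p = qc$hwe_p, call_rate = qc$call_rate,
                    set_id = set_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
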