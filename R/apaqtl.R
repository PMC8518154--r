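# cis apaQTL mapping from per-sample PAU matrices and genotype dosages:
# per-site standardization + inverse-normal quantile normalization, removal
# of top principal components, simple-regression cis scan, direct
# permutation lead-association FDR, and Storey pi1 sharing between result
# sets.  An eQTL scan is the same machinery with a wider cis window.

#' Standardize and inverse-normal quantile normalize a phenotype matrix
#'
#' Each site (column) is centered and scaled, then its values are replaced
#' by standard-normal quantiles `qnorm((rank - 0.5) / n)` with averaged
#' ranks for ties.  Standardization is order-preserving and therefore
#' redundant for the transform, but mirrors the usual two-step procedure.
#' Constant sites are dropped with a warning; missing values are kept
#' missing and ranked among the non-missing.
#'
#' @param mat numeric matrix, samples x sites.
#' @return matrix of the same shape (minus dropped columns).
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  const <- apply(mat, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) < 3L || stats::sd(x) == 0
  })
  if (any(const)) {
    warning(sum(const), " constant or near-empty site(s) dropped")
    mat <- mat[, !const, drop = FALSE]
  }
  apply(mat, 2, function(x) {
    ok <- !is.na(x)
    z <- scale(x[ok])[, 1]
    r <- rank(z, ties.method = "average")
    x[ok] <- stats::qnorm((r - 0.5) / sum(ok))
    x
  })
}

#' Regress top principal components out of a phenotype matrix
#'
#' Sample-space PCs of the (normalized) matrix are computed and the top
#' `n_pcs` regressed out of every site; residuals are re-standardized.
#'
#' @param mat numeric matrix, samples x sites (no missing values; impute or
#'   normalize first).
#' @param n_pcs number of components to remove (0 = identity).
#' @return residualized matrix of the same shape.
#' @export
remove_confounders <- function(mat, n_pcs = 4L) {
  mat <- as.matrix(mat)
  if (n_pcs >= nrow(mat))
    stop("n_pcs must be smaller than the number of samples", call. = FALSE)
  if (n_pcs == 0L) return(mat)
  if (anyNA(mat)) {
    mat <- apply(mat, 2, function(x) {
      x[is.na(x)] <- mean(x, na.rm = TRUE); x
    })
  }
  pcs <- stats::prcomp(mat, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                             drop = FALSE]
  res <- stats::lm.fit(cbind(1, pcs), mat)$residuals
  res <- apply(res, 2, function(x) if (stats::sd(x) > 0) scale(x)[, 1] else x)
  dimnames(res) <- dimnames(mat)
  res
}

#' Read a genotype matrix from VCF
#'
#' @param path VCF file (plain text or bgzipped).
#' @return list with `dosage` (samples x variants, 0/1/2, NA for missing)
#'   and `variants` data.frame (variant_id, chrom, position (0-based), ref,
#'   alt, maf).
#' @export
read_genotypes <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  count <- function(g) {
    if (g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  }
  for (v in seq_len(nrow(gt)))
    dos[, v] <- vapply(gt[v, ], count, 0)
  rr <- SummarizedExperiment::rowRanges(vcf)
  af <- colMeans(dos, na.rm = TRUE) / 2
  data <- data.frame(
    variant_id = rownames(gt),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    position = BiocGenerics::start(rr) - 1L,
    maf = pmin(af, 1 - af),
    stringsAsFactors = FALSE)
  list(dosage = dos, variants = data)
}

#' Nominal cis associations between PAU and genotype dosage
#'
#' For each site, every variant within `window` bp of the site position with
#' minor-allele frequency at least `maf_min` is tested by simple linear
#' regression of the transformed usage on dosage (missing dosages
#' mean-imputed per variant).
#'
#' @param mat phenotype matrix, samples x sites (normalized/residualized).
#' @param site_meta data.frame with site_id, chrom, position matching the
#'   matrix columns.
#' @param geno list from [read_genotypes()] (or same shape); sample rows are
#'   matched by name when both are named.
#' @param window cis window in bp (25 kb for apaQTL; 1 Mb for eQTL).
#' @param maf_min minimum minor-allele frequency.
#' @return data.frame: site_id, variant_id, distance, slope, t, p.
#' @export
cis_scan <- function(mat, site_meta, geno, window = 25000L, maf_min = 0.05) {
  mat <- as.matrix(mat)
  dos <- geno$dosage
  if (!is.null(rownames(mat)) && !is.null(rownames(dos))) {
    shared <- intersect(rownames(mat), rownames(dos))
    if (length(shared) == 0L) stop("no shared samples", call. = FALSE)
    mat <- mat[shared, , drop = FALSE]
    dos <- dos[shared, , drop = FALSE]
  }
  if (nrow(mat) != nrow(dos))
    stop("phenotype and genotype sample dimensions differ", call. = FALSE)
  dos <- apply(dos, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE); x
  })
  af <- colMeans(dos) / 2
  maf <- pmin(af, 1 - af)
  out <- list()
  n <- nrow(mat)
  for (j in seq_len(ncol(mat))) {
    sm <- site_meta[j, ]
    v <- which(geno$variants$chrom == sm$chrom &
                 abs(geno$variants$position - sm$position) <= window &
                 maf >= maf_min)
    if (length(v) == 0L) next
    y <- mat[, j]
    ok <- !is.na(y)
    yy <- y[ok]; G <- dos[ok, v, drop = FALSE]
    nn <- length(yy)
    sy <- stats::sd(yy)
    gsd <- apply(G, 2, stats::sd)
    usable <- gsd > 0
    if (!any(usable)) next
    G <- G[, usable, drop = FALSE]; vv <- v[usable]; gsd <- gsd[usable]
    r <- as.numeric(stats::cor(yy, G))
    slope <- r * sy / gsd
    tstat <- r * sqrt((nn - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = nn - 2, lower.tail = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      site_id = sm$site_id, variant_id = geno$variants$variant_id[vv],
      distance = geno$variants$position[vv] - sm$position,
      slope = slope, t = tstat, p = p, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(site_id = character(), variant_id = character(),
                      distance = integer(), slope = numeric(), t = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Minimum cis p-value per site for a block of permuted phenotypes.
# Y: n x (n_perm) matrix of permuted phenotype, G: n x m dosage block.
min_p_block <- function(Y, G) {
  n <- nrow(G)
  Ys <- scale(Y); Gs <- scale(G)
  r <- crossprod(Gs, Ys) / (n - 1)          # m x n_perm
  r2 <- pmin(r^2, 1 - 1e-12)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  apply(p, 2, min)
}

#' Lead-association permutation p-values and FDR calls
#'
#' For each site the lead (smallest nominal p) cis association is compared
#' against the null distribution of per-site minimum p-values obtained by
#' permuting sample labels: `perm_p = (1 + #{min cis p <= observed}) /
#' (n_perm + 1)`.  Sites are declared significant by Benjamini-Hochberg (or
#' Storey q-values) on the permutation p-values at the given FDR.
#'
#' @param mat,site_meta,geno,window,maf_min as in [cis_scan()].
#' @param n_perm number of permutations.
#' @param fdr FDR level for significance calls.
#' @param seed RNG seed for the permutations (required for reproducibility).
#' @param fdr_method `"BH"` or `"storey"`.
#' @return A `qtl_result` data.frame: site_id, lead_variant, slope,
#'   nominal_p, perm_p, qvalue, significant.
#' @export
lead_permutation_fdr <- function(mat, site_meta, geno, window = 25000L,
                                 maf_min = 0.05, n_perm = 1000L, fdr = 0.10,
                                 seed = 1L, fdr_method = c("BH", "storey")) {
  fdr_method <- match.arg(fdr_method)
  mat <- as.matrix(mat)
  nominal <- cis_scan(mat, site_meta, geno, window = window, maf_min = maf_min)
  if (nrow(nominal) == 0L)
    return(structure(data.frame(site_id = character(),
                                lead_variant = character(), slope = numeric(),
                                nominal_p = numeric(), perm_p = numeric(),
                                qvalue = numeric(), significant = logical()),
                     class = c("qtl_result", "data.frame"),
                     n_perm = n_perm, fdr = fdr, seed = seed))
  dos <- geno$dosage
  if (!is.null(rownames(mat)) && !is.null(rownames(dos))) {
    shared <- intersect(rownames(mat), rownames(dos))
    mat <- mat[shared, , drop = FALSE]
    dos <- dos[shared, , drop = FALSE]
  }
  dos <- apply(dos, 2, function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x })
  af <- colMeans(dos) / 2; maf <- pmin(af, 1 - af)
  n <- nrow(mat)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  sites <- unique(nominal$site_id)
  res <- vector("list", length(sites))
  for (si in seq_along(sites)) {
    sid <- sites[si]
    sub <- nominal[nominal$site_id == sid, , drop = FALSE]
    lead <- sub[which.min(sub$p), ]
    j <- match(sid, site_meta$site_id)
    sm <- site_meta[j, ]
    v <- which(geno$variants$chrom == sm$chrom &
                 abs(geno$variants$position - sm$position) <= window &
                 maf >= maf_min)
    G <- dos[, v, drop = FALSE]
    G <- G[, apply(G, 2, stats::sd) > 0, drop = FALSE]
    y <- mat[, j]
    y[is.na(y)] <- mean(y, na.rm = TRUE)
    Y <- matrix(y[perm_idx], nrow = n)
    minp <- min_p_block(Y, G)
    perm_p <- (1 + sum(minp <= lead$p)) / (n_perm + 1)
    res[[si]] <- data.frame(site_id = sid, lead_variant = lead$variant_id,
                            slope = lead$slope, nominal_p = lead$p,
                            perm_p = perm_p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  if (fdr_method == "BH") {
    res$qvalue <- stats::p.adjust(res$perm_p, method = "BH")
  } else {
    res$qvalue <- storey_qvalue(res$perm_p)
  }
  res$significant <- res$qvalue < fdr
  structure(res, class = c("qtl_result", "data.frame"),
            n_perm = n_perm, fdr = fdr, seed = seed)
}

#' @export
print.qtl_result <- function(x, ...) {
  cat(sprintf("qtl_result: %d sites scanned, %d significant at FDR %.2f (%d permutations, seed %s)\n",
              nrow(x), sum(x$significant), attr(x, "fdr"),
              attr(x, "n_perm"), attr(x, "seed")))
  invisible(x)
}

#' @export
summary.qtl_result <- function(object, ...) {
  cat("Lead cis associations per site\n")
  print.qtl_result(object)
  if (nrow(object) > 0L) {
    cat("perm_p quantiles:\n")
    print(stats::quantile(object$perm_p, c(0, 0.25, 0.5, 0.75, 1)))
  }
  invisible(object)
}

# Storey pi0 estimate on a lambda grid with cubic-spline smoothing
# (df = 3), read at the largest lambda; fixed lambda = 0.5 for small m.
storey_pi0 <- function(p, lambdas = seq(0.05, 0.90, by = 0.05)) {
  m <- length(p)
  if (m < 100L) {
    lam <- 0.5
    return(min(1, max(0, mean(p > lam) / (1 - lam))))
  }
  pi0l <- vapply(lambdas, function(l) mean(p > l) / (1 - l), 0)
  fit <- stats::smooth.spline(lambdas, pi0l, df = 3)
  min(1, max(0, stats::predict(fit, x = max(lambdas))$y))
}

storey_qvalue <- function(p) {
  m <- length(p)
  pi0 <- storey_pi0(p)
  o <- order(p)
  q <- pi0 * p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m); out[o] <- pmin(q, 1)
  out
}

#' Storey pi1 sharing between a discovery and a replication scan
#'
#' Takes the replication nominal p-values of the discovery lead pairs and
#' estimates the fraction of true associations among them as
#' `pi1 = 1 - pi0`, with `pi0` from Storey's lambda-grid estimator
#' (spline-smoothed; fixed lambda 0.5 below 100 pairs).
#'
#' @param replication_p numeric vector of replication p-values for the
#'   discovery lead SNP-site pairs.
#' @return list with `pi1`, `pi0` and `n_pairs`; a warning flags fewer than
#'   20 pairs (wide uncertainty).
#' @export
pi1_sharing <- function(replication_p) {
  replication_p <- replication_p[!is.na(replication_p)]
  if (length(replication_p) == 0L)
    stop("empty replication set", call. = FALSE)
  if (length(replication_p) < 20L)
    warning("fewer than 20 pairs; pi1 estimate has wide uncertainty")
  pi0 <- storey_pi0(replication_p)
  list(pi1 = min(1, max(0, 1 - pi0)), pi0 = pi0,
       n_pairs = length(replication_p))
}
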