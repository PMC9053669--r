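# Independent oracles, written against the definitions rather than the
# package's code paths.

# Two-sided Fisher p by direct enumeration with binomial coefficients.
oracle_fisher_p <- function(a, b, c, d, rel_eps = 1e-7) {
  k <- a + b; m <- a + c; n <- b + d
  supp <- max(0, k - n):min(k, m)
  pr <- choose(m, supp) * choose(n, k - supp)
  pr <- pr / sum(pr)
  obs <- pr[supp == a]
  min(1, sum(pr[pr <= obs * (1 + rel_eps)]))
}

# Noncentral hypergeometric pmf by enumeration (choose(), not dhyper).
oracle_nchg_pmf <- function(a, b, c, d, psi) {
  k <- a + b; m <- a + c; n <- b + d
  supp <- max(0, k - n):min(k, m)
  w <- choose(m, supp) * choose(n, k - supp) * psi^supp
  list(support = supp, pmf = w / sum(w))
}

# Conditional-MLE OR by solving E[A] = a with stats::uniroot on the
# enumeration pmf.
oracle_cmle <- function(a, b, c, d) {
  k <- a + b; m <- a + c; n <- b + d
  lo <- max(0, k - n); hi <- min(k, m)
  if (lo == hi) return(NA_real_)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  f <- function(lp) {
    e <- oracle_nchg_pmf(a, b, c, d, exp(lp))
    sum(e$support * e$pmf) - a
  }
  exp(stats::uniroot(f, c(log(1e-10), log(1e10)), tol = 1e-12)$root)
}

# Exact tail-inversion CI on the enumeration pmf.
oracle_ci <- function(a, b, c, d, alpha = 0.05) {
  k <- a + b; m <- a + c; n <- b + d
  lo_s <- max(0, k - n); hi_s <- min(k, m)
  upper_tail <- function(psi) {
    e <- oracle_nchg_pmf(a, b, c, d, psi)
    sum(e$pmf[e$support >= a])
  }
  lower_tail <- function(psi) {
    e <- oracle_nchg_pmf(a, b, c, d, psi)
    sum(e$pmf[e$support <= a])
  }
  lower <- if (a == lo_s) 0 else
    exp(stats::uniroot(function(lp) upper_tail(exp(lp)) - alpha / 2,
                       c(log(1e-10), log(1e10)), tol = 1e-12)$root)
  upper <- if (a == hi_s) Inf else
    exp(stats::uniroot(function(lp) lower_tail(exp(lp)) - alpha / 2,
                       c(log(1e-10), log(1e10)), tol = 1e-12)$root)
  c(lower, upper)
}

# All-pairs brute-force CNV/gene overlap under half-open arithmetic.
oracle_overlap <- function(cnvs, genes) {
  genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cnvs))) for (j in seq_len(nrow(genes))) {
    if (cnvs$chrom[i] == genes$chrom[j] &&
        max(cnvs$start[i], genes$start[j]) < min(cnvs$end[i], genes$end[j])) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cnvs$sample_id[i], gene_id = genes$gene_id[j],
        dosage = as.character(cnvs$dosage[i]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sample_id = character(0), gene_id = character(0),
                      dosage = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  out[order(out$sample_id, out$gene_id, out$dosage), , drop = FALSE]
}

write_tsv_fixture <- function(df, dir = tempdir(), name = "fixture.tsv") {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

new_cohort_for_test <- function(ids) {
  n <- length(ids)
  mirCNVburden:::new_cohort(ids,
                            rep(c("CASE", "CONTROL"), length.out = n),
                            rep(c("FEMALE", "MALE"), length.out = n))
}
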