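# small study configuration used across tests: same structure as the default
# conditions, scaled to 2 x 10 genes and a few thousand tags per sample
tiny_config <- function(seed = 7, ...) {
  pat_sim_config(genes_per_chromosome = 10, depth_per_sample = 4000,
                 seed = seed, ...)
}

random_genome <- function(len, seed = 1) {
  withr::with_seed(seed, {
    setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = ""), "chr1")
  })
}

# mRNA-sense tag of length L ending at database position j of record i
sense_tag <- function(db, i, j, L = 50) {
  sense <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(db$db_seq[i])))
  substr(sense, db$db_length[i] - j - L + 1, db$db_length[i] - j)
}

as_read_tbl <- function(sequence, read_id = sprintf("r%03d", seq_along(sequence))) {
  tibble::tibble(read_id = read_id, sequence = sequence,
                 quality = strrep("I", nchar(sequence)))
}

# exhaustive-permutation two-sided rank-sum p-value: enumerate every split of
# the pooled values into groups of the observed sizes and count rank sums as
# or more extreme than the observed one on the shorter tail
perm_wilcox_p <- function(x, y) {
  ranks <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(ranks[seq_len(n1)])
  splits <- utils::combn(length(ranks), n1)
  w_all <- apply(splits, 2, function(idx) sum(ranks[idx]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# independently coded weighted proportions test (scalar arithmetic, no
# matrix code shared with the implementation)
baggerly_oracle <- function(xa, na, xb, nb) {
  grp <- function(x, n) {
    m <- length(x)
    N <- sum(n)
    p <- x / n
    w <- n / N
    ph <- sum(w * p)
    vw <- ph * (1 - ph) / N
    vb <- 0
    if (m > 1) {
      s2 <- sum(w * (p - ph)^2) / (1 - sum(w^2))
      vb <- s2 * sum(w^2)
    }
    list(ph = ph, v = vw + vb, m = m)
  }
  a <- grp(xa, na)
  b <- grp(xb, nb)
  se <- sqrt(a$v + b$v)
  stat <- if (se > 0) (a$ph - b$ph) / se else 0
  df <- a$m + b$m - 2
  p <- if (df >= 1) 2 * stats::pt(-abs(stat), df) else 2 * stats::pnorm(-abs(stat))
  list(statistic = stat, df = df, p_value = min(p, 1))
}

# profiles drawn straight from generator truth: per gene and sample,
# multinomial site counts around Poisson-distributed gene totals
profiles_from_truth <- function(reference, samples = NULL, depth_factor = 1,
                                seed = 1) {
  cfg <- reference$config
  samples <- samples %||% cfg$barcode_table
  sites <- reference$truth$sites
  usage <- reference$truth$usage
  expr <- reference$truth$expression
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(samples)), function(si) {
      g <- samples$genotype[si]
      purrr::map_dfr(unique(sites$gene_id), function(gid) {
        st <- sites[sites$gene_id == gid, ]
        us <- usage[usage$gene_id == gid & usage$genotype == g, ]
        mu <- expr$mean_count[expr$gene_id == gid & expr$genotype == g]
        n <- stats::rpois(1, mu * depth_factor)
        if (n == 0) return(NULL)
        cnt <- as.vector(stats::rmultinom(1, n, us$usage))
        keep <- cnt > 0
        tibble::tibble(gene_id = gid, sample = samples$sample[si],
                       site = st$genomic_pos[keep], count = cnt[keep],
                       usage = cnt[keep] / n)
      })
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
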