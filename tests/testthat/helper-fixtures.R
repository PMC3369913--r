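# Shared fixture builders. Everything is generated in code; no binary data.

random_nt <- function(n, chars = c("A", "C", "G", "T")) {
  paste(sample(chars, n, replace = TRUE), collapse = "")
}

random_record_set <- function(n_rec, len, alphabet = "nt",
                              chars = c("A", "C", "G", "T")) {
  build_aligned_set(lapply(seq_len(n_rec), function(i) {
    seq_record(paste0("t", i), random_nt(len, chars), alphabet)
  }))
}

# site-by-site brute-force p-distance oracle (independent of the package path)
oracle_p_distance <- function(a, b, resolved = c("A", "C", "G", "T")) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  diff <- 0L; comp <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% resolved && bv[i] %in% resolved) {
      comp <- comp + 1L
      if (av[i] != bv[i]) diff <- diff + 1L
    }
  }
  if (comp == 0L) NA_real_ else diff / comp
}

# brute-force Mann-Whitney exact two-sided p by full labeling enumeration
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# a 60-position amino-acid "homeodomain" panel pair that differs only at the
# given positions (synthetic stand-in for real Scr/Antp reference sequences)
make_scr_antp_panels <- function(diff_positions = c(1, 4, 6, 7, 60),
                                 n_members = 3, seed = 101) {
  set.seed(seed)
  aa <- setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], character(0))
  backbone <- sample(aa, 60, replace = TRUE)
  scr_chars <- backbone
  antp_chars <- backbone
  for (p in diff_positions) {
    pair <- sample(aa, 2)            # disjoint residue sets at this position
    scr_chars[p] <- pair[1]
    antp_chars[p] <- pair[2]
  }
  mk <- function(chars, fam) {
    lapply(seq_len(n_members), function(i) {
      v <- chars
      seq_record(sprintf("%s_%d", fam, i), paste(v, collapse = ""), "aa")
    })
  }
  list(Scr = hox_panel("Scr", mk(scr_chars, "Scr")),
       Antp = hox_panel("Antp", mk(antp_chars, "Antp")),
       scr_consensus = paste(scr_chars, collapse = ""),
       antp_consensus = paste(antp_chars, collapse = ""))
}

# a query restricted to homeodomain positions 20-45 (everything else masked)
window_query <- function(full_sequence, from = 20, to = 45, id = "frag") {
  chars <- strsplit(full_sequence, "")[[1]]
  masked <- rep("-", length(chars))
  masked[from:to] <- chars[from:to]
  seq_record(id, paste(masked, collapse = ""), "aa")
}

# small precomputed-distance rows for pipeline tests
toy_summaries <- function() {
  data.frame(gene = c("lab", "lab"),
             group = c("Insecta", "Gastropoda"),
             super_label = c("insect", "non-insect"),
             n_taxa = c(9L, 5L), n_sites = c(75L, 75L),
             mean_p_percent = c(26, 32),
             stringsAsFactors = FALSE)
}
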