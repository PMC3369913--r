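# Star-phylogeny simulator for study-shaped homeobox fragment sets. Each
# group radiates from one random ancestral fragment; every lineage receives
# an independent Poisson number of uniform-replacement substitutions per
# site, sized so a PAIR of lineages accumulates the target divergence
# rate * age (the fossil age bounds the pairwise split, so each lineage
# carries half of it).

state_space <- function(alphabet) {
  switch(match.arg(alphabet, c("nt", "aa")),
         nt = c("A", "C", "G", "T"),
         aa = setdiff(AA_CHARS, c("X", "-", "?", "*")))
}

# Under a uniform jump chain over S states, a lineage hit by Poisson(lambda)
# substitutions per site differs from its ancestor with probability
# c * (1 - exp(-lambda / c)), c = (S - 1) / S; two independent lineages
# differ with the same formula at 2 * lambda.
pair_lambda <- function(target_p, n_states, saturation_model) {
  cmax <- (n_states - 1) / n_states
  if (saturation_model == "linear") {
    # invert so the EXPECTED pairwise p-distance equals the target exactly
    if (target_p >= cmax) {
      stop("saturated: target expected p-distance ", signif(target_p, 4),
           " >= ", signif(cmax, 4))
    }
    -cmax * log(1 - target_p / cmax) / 2
  } else {
    # target is expected substitutions per site of the pair; realized
    # p-distance saturates as p = c (1 - exp(-d / c)) and a nominal target
    # at or beyond the saturation plateau is rejected
    if (target_p >= cmax) {
      stop("saturated: target ", signif(target_p, 4), " >= ",
           signif(cmax, 4), " under jukes-cantor")
    }
    target_p / 2
  }
}

#' Simulate one group of aligned homeobox fragments (star phylogeny)
#'
#' Draws a uniform random ancestral fragment of length `sites` and evolves
#' `n_taxa` lineages independently. Per lineage and site the substitution
#' count is Poisson with uniform replacement among the remaining states, so
#' under `saturation_model = "linear"` the expected pairwise p-distance
#' equals `rate * age_my / 100` exactly, while `"jukes-cantor"` treats that
#' quantity as expected substitutions per site and lets the observable
#' p-distance saturate as `p = 0.75 (1 - exp(-4/3 d))` (nucleotides).
#'
#' @param label Group label (also the taxon-id prefix).
#' @param n_taxa Number of lineages (>= 2).
#' @param sites Fragment length L in sites (default 75, the modal site
#'   count of homeodomain-fragment analyses).
#' @param age_my Fossil calibration age in My.
#' @param rate True divergence rate in percent per My.
#' @param saturation_model `"linear"` or `"jukes-cantor"`.
#' @param alphabet `"nt"` (default) or `"aa"`.
#' @param seed Optional integer; when given, seeds the RNG for a
#'   reproducible draw.
#' @return An [aligned_set] with taxon ids `<label>_t1 ...`; the ancestral
#'   sequence is attached as `attr(, "ancestor")`.
#' @export
simulate_group <- function(label, n_taxa, sites = 75L, age_my, rate,
                           saturation_model = c("linear", "jukes-cantor"),
                           alphabet = "nt", seed = NULL) {
  saturation_model <- match.arg(saturation_model)
  stopifnot(n_taxa >= 2L, sites >= 1L, age_my > 0, rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  states <- state_space(alphabet)
  S <- length(states)
  target_p <- rate * age_my / 100
  lambda <- if (rate == 0) 0 else pair_lambda(target_p, S, saturation_model)
  anc <- sample(states, sites, replace = TRUE)
  records <- vector("list", n_taxa)
  for (t in seq_len(n_taxa)) {
    seqv <- anc
    k <- stats::rpois(sites, lambda)
    pending <- which(k > 0L)
    while (length(pending)) {
      # one uniform jump to a different state at every pending site
      repl <- vapply(seqv[pending], function(cur) {
        sample(setdiff(states, cur), 1L)
      }, character(1L))
      seqv[pending] <- repl
      k[pending] <- k[pending] - 1L
      pending <- pending[k[pending] > 0L]
    }
    records[[t]] <- seq_record(sprintf("%s_t%d", label, t),
                               paste(seqv, collapse = ""),
                               alphabet = alphabet)
  }
  out <- build_aligned_set(records)
  attr(out, "ancestor") <- paste(anc, collapse = "")
  out
}

#' Default study-shaped simulation specification
#'
#' One row per (gene, group) mirroring the structure of the published rate
#' table: the same genes, groups, taxon counts, site counts and fossil
#' ages, with true rates 0.06 %/My for insect rows and 0.04 %/My for
#' non-insect rows (the two published super-group means).
#'
#' @param insect_rate,noninsect_rate True rates in percent per My.
#' @return Data.frame: `gene`, `group`, `super_label`, `n_taxa`, `n_sites`,
#'   `age_my`, `true_rate`.
#' @export
default_simulation_spec <- function(insect_rate = 0.06, noninsect_rate = 0.04) {
  tab <- load_hox_divergence_table()
  data.frame(gene = tab$gene, group = tab$group,
             super_label = tab$super_label,
             n_taxa = tab$n_taxa, n_sites = tab$n_sites,
             age_my = tab$age_my,
             true_rate = ifelse(tab$super_label == "insect",
                                insect_rate, noninsect_rate),
             stringsAsFactors = FALSE)
}

#' Generate a complete pipeline-ready input bundle
#'
#' Simulates every (gene, group) row of `spec`, writing one FASTA per gene,
#' a taxon-to-group TSV, a calibration TSV and a JSON manifest of the
#' ground-truth parameters (for recovery testing). All randomness flows
#' from `seed`; identical calls are bit-reproducible.
#'
#' @param spec Data.frame as from [default_simulation_spec()] (groups with
#'   n_taxa >= 2; non-empty).
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param saturation_model Passed to [simulate_group()].
#' @param alphabet `"nt"` or `"aa"`.
#' @return Invisibly, a list with `dir`, `fasta` (named per-gene paths),
#'   `groups_tsv`, `calibration_tsv`, `manifest`.
#' @export
generate_study_fixture <- function(spec, dir, seed = 1L,
                                   saturation_model = "linear",
                                   alphabet = "nt") {
  if (nrow(spec) == 0L) stop("empty group list in simulation spec")
  need <- c("gene", "group", "super_label", "n_taxa", "n_sites", "age_my",
            "true_rate")
  if (!all(need %in% names(spec))) {
    stop("spec must have columns: ", paste(need, collapse = ", "))
  }
  if (any(spec$n_taxa < 2L)) stop("every simulated group needs n_taxa >= 2")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  fasta_paths <- character(0)
  group_rows <- list()
  for (g in unique(spec$gene)) {
    rows <- spec[spec$gene == g, , drop = FALSE]
    sets <- list()
    for (r in seq_len(nrow(rows))) {
      lab <- sprintf("%s_%s", g, gsub("[^A-Za-z0-9]+", ".", rows$group[r]))
      sim <- simulate_group(lab, rows$n_taxa[r], rows$n_sites[r],
                            rows$age_my[r], rows$true_rate[r],
                            saturation_model = saturation_model,
                            alphabet = alphabet)
      sets[[r]] <- sim
      group_rows[[length(group_rows) + 1L]] <-
        data.frame(taxon_id = set_ids(sim), group = rows$group[r],
                   super_label = rows$super_label[r], gene = g,
                   stringsAsFactors = FALSE)
    }
    path <- file.path(dir, paste0(g, ".fasta"))
    write_fasta(do.call(c, lapply(sets, function(s) s$records)), path)
    fasta_paths[[g]] <- path
  }
  groups_df <- do.call(rbind, group_rows)
  groups_tsv <- file.path(dir, "groups.tsv")
  utils::write.table(groups_df, groups_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cal <- read_calibration_table()
  cal <- cal[cal$group %in% spec$group, , drop = FALSE]
  calibration_tsv <- file.path(dir, "calibrations.tsv")
  utils::write.table(cal, calibration_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(seed = seed, saturation_model = saturation_model,
                   alphabet = alphabet,
                   truth = spec)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(dir = dir, fasta = fasta_paths, groups_tsv = groups_tsv,
                 calibration_tsv = calibration_tsv, manifest = manifest_path))
}
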