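# Synthetic data: clock-evolving domain clades with a controllable internal
# duplication, and multi-LBD gene-model fixtures with known linker lengths.
#
# Rate convention (documented prominently because it is easy to get wrong):
# the clade rate r is defined on the PAIRWISE path, d(a, b) = r * T(a, b),
# matching a regression of pairwise distance on divergence time. On the
# star tree used here each lineage therefore evolves r * t_i with tip age
# t_i, and t_a + t_b = T(a, b) (t_i = T / 2 for an ultrametric clade).

#' Specification of a simulated clock-evolving clade
#'
#' @param n_taxa number of taxa (>= 2).
#' @param divergence_times either a single time in Myr (ultrametric: every
#'   pair diverged then) or a data.frame `taxon_a`/`taxon_b`/`time_mya`
#'   covering all pairs. Non-ultrametric tables must be star-additive
#'   (`T(a,b) = t_a + t_b` for some tip ages `t_i >= 0`), which is checked.
#' @param r_true clade rate, substitutions/site/Myr on the pairwise-path
#'   convention.
#' @param dup_taxon optional taxon carrying an internal domain duplication.
#' @param d_dup_true expected path length (substitutions/site) between the
#'   two domain copies of `dup_taxon`.
#' @param seq_length number of sites (>= 1).
#' @param gamma_alpha shape of across-site rate variation (Inf = none).
#' @param gamma_k discrete-gamma categories.
#' @param seed RNG seed.
#' @return validated list of class `clade_sim_spec`.
#' @export
clade_sim_spec <- function(n_taxa = 5L, divergence_times = 100,
                           r_true = 0.001, dup_taxon = NULL, d_dup_true = 0,
                           seq_length = 10000L, gamma_alpha = 1.0,
                           gamma_k = 4L, seed = NULL) {
  if (!is.numeric(n_taxa) || n_taxa < 2 || n_taxa != round(n_taxa))
    abort_field("n_taxa", "must be an integer >= 2")
  n_taxa <- as.integer(n_taxa)
  taxa <- paste0("t", seq_len(n_taxa))
  if (is.data.frame(divergence_times)) {
    if (any(divergence_times$time_mya <= 0))
      abort_field("divergence_times", "all times must be > 0")
    times <- divergence_times
  } else {
    assert_scalar_num(divergence_times, "divergence_times", lower = 0,
                      strict = TRUE)
    pairs <- utils::combn(taxa, 2)
    times <- data.frame(taxon_a = pairs[1, ], taxon_b = pairs[2, ],
                        time_mya = divergence_times)
  }
  assert_scalar_num(r_true, "r_true", lower = 0)
  assert_scalar_num(d_dup_true, "d_dup_true", lower = 0)
  assert_scalar_num(seq_length, "seq_length", lower = 1)
  seq_length <- as.integer(seq_length)
  assert_scalar_num(gamma_alpha, "gamma_alpha", lower = 0, strict = TRUE,
                    allow_inf = TRUE)
  if (!is.null(dup_taxon) && !dup_taxon %in% taxa)
    abort_field("dup_taxon", sprintf("'%s' is not one of %s", dup_taxon,
                                     paste(taxa, collapse = ", ")))
  tip_ages <- solve_tip_ages(taxa, times)
  structure(list(n_taxa = n_taxa, taxa = taxa, divergence_times = times,
                 tip_ages = tip_ages, r_true = r_true, dup_taxon = dup_taxon,
                 d_dup_true = d_dup_true, seq_length = seq_length,
                 gamma_alpha = gamma_alpha, gamma_k = as.integer(gamma_k),
                 seed = seed),
            class = "clade_sim_spec")
}

# Least-squares tip ages t_i with T(a,b) ~= t_a + t_b; errors if the table is
# not star-additive (relative residual > 1%) or implies negative ages.
solve_tip_ages <- function(taxa, times) {
  n <- length(taxa)
  m <- nrow(times)
  A <- matrix(0, m, n, dimnames = list(NULL, taxa))
  for (i in seq_len(m)) {
    ia <- match(times$taxon_a[i], taxa); ib <- match(times$taxon_b[i], taxa)
    if (is.na(ia) || is.na(ib))
      abort_field("divergence_times", "unknown taxon in table")
    A[i, ia] <- 1; A[i, ib] <- 1
  }
  # minimum-norm least squares via SVD (handles the underdetermined
  # two-taxon case, where any split t_a + t_b = T is admissible)
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-10
  t <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% times$time_mya) / sv$d[keep])
  t <- as.numeric(t)
  resid <- times$time_mya - A %*% t
  if (max(abs(resid)) > 0.01 * max(times$time_mya))
    abort_field("divergence_times",
                "pairwise times are not star-additive (T(a,b) = t_a + t_b)")
  if (any(t < -1e-8))
    abort_field("divergence_times", "implied tip ages are negative")
  stats::setNames(pmax(as.numeric(t), 0), taxa)
}

# Evolve a parent index vector along a path of expected length d, given the
# per-site gamma category rates.
evolve_seq <- function(parent_idx, d, site_rates) {
  if (d == 0) return(parent_idx)
  child <- parent_idx
  groups <- split(seq_along(parent_idx),
                  list(aa = parent_idx, r = site_rates), drop = TRUE)
  for (g in groups) {
    aa <- parent_idx[g[1]]
    t <- d * site_rates[g[1]]
    P <- jtt_prob(t)
    child[g] <- sample.int(20, length(g), replace = TRUE, prob = P[aa, ])
  }
  child
}

idx_to_seq <- function(idx) paste(AA_LEVELS[idx], collapse = "")

#' Simulate a clock-evolving clade of protein domains
#'
#' Sequences evolve from a stationary root on a star tree under JTT with
#' discrete-gamma site rates, so the expected estimator path length for each
#' pair equals `r_true * T(a, b)`. When `dup_taxon` is set, that taxon
#' carries a second domain copy at expected path length `d_dup_true` from its
#' first copy (records `<taxon>_in` and `<taxon>_out`).
#'
#' @param spec a [clade_sim_spec()].
#' @return list with `records` (named list of [protein_record()]s),
#'   `divergence_table`, and `truth` (tip ages, expected pairwise path
#'   lengths, `d_dup_true`, the spec, and the root sequence).
#' @export
simulate_clade <- function(spec) {
  if (!inherits(spec, "clade_sim_spec"))
    abort_field("spec", "must be a clade_sim_spec")
  gm <- gamma_model(spec$gamma_alpha, spec$gamma_k)
  res <- with_seed(spec$seed, {
    L <- spec$seq_length
    site_rates <- gm$rates[sample.int(gm$k, L, replace = TRUE)]
    root <- sample.int(20, L, replace = TRUE, prob = jtt_model()$pi)
    seqs <- lapply(spec$tip_ages[spec$taxa], function(t)
      evolve_seq(root, spec$r_true * t, site_rates))
    names(seqs) <- spec$taxa
    dup <- NULL
    if (!is.null(spec$dup_taxon)) {
      # the duplicated copy diverges from the taxon's own domain; site rates
      # are shared along that path so the pair estimator is well-posed
      dup_rates <- gm$rates[sample.int(gm$k, L, replace = TRUE)]
      dup <- evolve_seq(seqs[[spec$dup_taxon]], spec$d_dup_true, dup_rates)
    }
    list(root = root, seqs = seqs, dup = dup)
  })
  # taxon records keep the taxon name as id (so divergence-time lookup works);
  # the duplicated copy of dup_taxon is a separate `<taxon>_dup` record.
  records <- list()
  for (tx in spec$taxa) {
    records[[tx]] <- protein_record(tx, idx_to_seq(res$seqs[[tx]]),
                                    species = tx)
  }
  if (!is.null(res$dup)) {
    id <- paste0(spec$dup_taxon, "_dup")
    records[[id]] <- protein_record(id, idx_to_seq(res$dup),
                                    species = spec$dup_taxon)
  }
  expected <- spec$divergence_times
  expected$expected_d <- spec$r_true * expected$time_mya
  list(records = records,
       divergence_table = spec$divergence_times,
       truth = list(tip_ages = spec$tip_ages,
                    expected_paths = expected,
                    d_dup_true = if (is.null(spec$dup_taxon)) NA_real_
                                 else spec$d_dup_true,
                    dup_taxon = spec$dup_taxon,
                    root = idx_to_seq(res$root),
                    spec = spec))
}

#' Write a simulated clade to disk (FASTA + divergence TSV + truth JSON)
#'
#' @param sim result of [simulate_clade()].
#' @param out_dir output directory (created if needed).
#' @export
write_clade <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$records, file.path(out_dir, "domains.fa"))
  write_tsv(sim$divergence_table, file.path(out_dir, "divergence_times.tsv"))
  truth <- sim$truth
  truth$spec <- NULL
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# --- gene-model fixtures ----------------------------------------------------

# Codon table: first codon listed for each amino acid in the standard code.
codon_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  vapply(AA_LEVELS, function(aa) names(gc)[gc == aa][1], character(1))
}

random_aa <- function(n) paste(sample(AA_LEVELS, n, replace = TRUE,
                                      prob = jtt_model()$pi), collapse = "")

#' Synthetic multi-exon gene model with tandem LBDs
#'
#' Builds a contig, exon structure and protein emulating a type II receptor
#' whose LBD is split across an exon pair; with `two_lbd = TRUE` the exon
#' pair is duplicated and the requested number of linker residues is encoded
#' at the junction between the original second exon and the duplicated first
#' exon (the E3-E2' junction of an exon-pair duplication).
#'
#' @param two_lbd duplicate the domain exon pair?
#' @param linker_len residues between the two domain copies (>= 0).
#' @param domain_len domain length in residues.
#' @param seed RNG seed.
#' @return list `gene_model_fixture`: `contig` (DNA string), `exons`
#'   (data.frame, 0-based half-open contig coordinates), `protein`
#'   ([protein_record()]), `domains` (`domain_annotation`-style data.frame),
#'   `linker_len` (NA for single-LBD models).
#' @export
make_gene_model <- function(two_lbd = TRUE, linker_len = 20L,
                            domain_len = 60L, seed = NULL) {
  assert_flag(two_lbd, "two_lbd")
  assert_scalar_num(linker_len, "linker_len", lower = 0)
  linker_len <- as.integer(linker_len)
  with_seed(seed, {
    nflank <- random_aa(25)                     # signal peptide / N-terminus
    domain <- random_aa(domain_len)
    linker <- if (linker_len > 0) random_aa(linker_len) else ""
    cflank <- random_aa(40)                     # TM + kinase stand-in
    if (two_lbd) {
      protein_seq <- paste0(nflank, domain, linker, domain, cflank)
      dom_starts <- c(25L, 25L + domain_len + linker_len)
    } else {
      protein_seq <- paste0(nflank, domain, cflank)
      dom_starts <- 25L
    }
    prot <- protein_record("synthetic_receptor", protein_seq)

    codons <- codon_for()
    aa <- strsplit(protein_seq, "", fixed = TRUE)[[1]]
    cds <- paste(codons[aa], collapse = "")

    # exon layout (protein residue counts per exon, codon-aligned splits):
    # E1 = N-flank; each domain spans an exon pair split mid-domain, with the
    # linker carried by the 3' end of the first pair's second exon and the
    # 5' end of the duplicated first exon; final exon = C-flank.
    half <- domain_len %/% 2L
    lh <- linker_len %/% 2L
    if (two_lbd) {
      res_per_exon <- c(25L, half, domain_len - half + lh,
                        linker_len - lh + half, domain_len - half, 40L)
    } else {
      res_per_exon <- c(25L, half, domain_len - half, 40L)
    }
    res_per_exon <- res_per_exon[res_per_exon > 0]
    intron_len <- 100L
    introns <- vapply(seq_along(res_per_exon)[-1], function(i)
      paste(sample(c("a", "c", "g", "t"), intron_len, replace = TRUE),
            collapse = ""), character(1))
    exon_nt <- res_per_exon * 3L
    contig_parts <- character(0)
    exon_rows <- list()
    pos <- 0L
    cds_off <- 0L
    for (i in seq_along(exon_nt)) {
      exon_seq <- substr(cds, cds_off + 1L, cds_off + exon_nt[i])
      contig_parts <- c(contig_parts, exon_seq)
      exon_rows[[i]] <- data.frame(exon = paste0("E", i), start = pos,
                                   end = pos + exon_nt[i])
      pos <- pos + exon_nt[i]
      cds_off <- cds_off + exon_nt[i]
      if (i < length(exon_nt)) {
        contig_parts <- c(contig_parts, introns[i])
        pos <- pos + intron_len
      }
    }
    contig <- paste(contig_parts, collapse = "")
    exons <- do.call(rbind, exon_rows)

    n_dom <- if (two_lbd) 2L else 1L
    domains <- data.frame(protein_id = prot$id, start = dom_starts,
                          end = dom_starts + domain_len,
                          start_1based = dom_starts + 1L,
                          end_1based = dom_starts + domain_len,
                          order_index = seq_len(n_dom),
                          label = domain_labels(n_dom),
                          score = NA_real_)
    class(domains) <- c("domain_annotation", "data.frame")
    structure(list(contig = contig, exons = exons, protein = prot, cds = cds,
                   domains = domains,
                   linker_len = if (two_lbd) linker_len else NA_integer_),
              class = "gene_model_fixture")
  })
}

#' Translate the CDS of a gene-model fixture
#'
#' Concatenates the exon sequences from the contig and translates them;
#' used to assert translation consistency of fixtures.
#' @param fixture a `gene_model_fixture`.
#' @return amino-acid string.
#' @export
translate_gene_model <- function(fixture) {
  cds <- paste(vapply(seq_len(nrow(fixture$exons)), function(i)
    substr(fixture$contig, fixture$exons$start[i] + 1L, fixture$exons$end[i]),
    character(1)), collapse = "")
  as.character(Biostrings::translate(Biostrings::DNAString(toupper(cds))))
}
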