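# Synthetic stand-ins for the published benchmark tables.  The real
# curated datasets (a 303-mutation stability benchmark, a 65-pair
# forward/back mutation set, and a paired-conformation database subset) are
# external downloads; these generators emit tables with the same layout and
# the same published composition so the handling machinery -- threshold
# classification, exclusion lists, directed expansion -- can be exercised
# end to end.  Every value in them is synthetic.

.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' Synthetic mutation stability table
#'
#' One mutation per row (PDB id, chain, wild-type residue, position, mutant
#' residue, experimental ddG in kcal/mol), mirroring the layout of the
#' curated stability benchmark.  The default composition matches the
#' published dataset: 45 stabilizing (ddG < -0.5), 84 neutral (closed
#' interval [-0.5, 0.5]) and 174 destabilizing (ddG > 0.5) mutations, 303
#' rows in total.  All identifiers and values are synthetic.
#'
#' @param n_stabilizing,n_neutral,n_destabilizing Class sizes.
#' @param seed RNG seed.
#' @return A data frame with columns `pdb_id`, `chain`, `wt_res`,
#'   `position`, `mut_res`, `ddg_exp`.
#' @export
synthetic_mutation_table <- function(n_stabilizing = 45L, n_neutral = 84L,
                                     n_destabilizing = 174L, seed = 1L) {
  df <- .with_seed(seed, {
    ddg <- c(-0.5 - stats::rexp(n_stabilizing, rate = 1),
             stats::runif(n_neutral, -0.5, 0.5),
             0.5 + stats::rexp(n_destabilizing, rate = 0.7))
    n <- length(ddg)
    pdbs <- sprintf("SYN%02d", 1:20)
    out <- data.frame(
      pdb_id = sample(pdbs, n, replace = TRUE),
      chain = "A",
      wt_res = sample(.aa1, n, replace = TRUE),
      position = sample.int(150L, n, replace = TRUE),
      mut_res = sample(.aa1, n, replace = TRUE),
      ddg_exp = ddg,
      stringsAsFactors = FALSE)
    out[sample.int(n, n), , drop = FALSE]
  })
  rownames(df) <- NULL
  df
}

#' Synthetic forward/back self-consistency table
#'
#' Pairs of structures related by a single mutation, with predictions for
#' the forward (A to B) and back (B to A) direction, mirroring the layout
#' of the published self-consistency set: 65 pairs of which 3 involve
#' prolines (excluded because they alter the backbone) and 5 failed on an
#' external server, leaving 57 analysable pairs after exclusions.
#'
#' @param n_pairs Total number of pairs.
#' @param n_proline Pairs flagged for the proline exclusion.
#' @param n_failures Pairs flagged as external-server failures.
#' @param antisym_noise Standard deviation of the deviation from perfect
#'   antisymmetry injected into the back predictions.
#' @param seed RNG seed.
#' @return A data frame with columns `pair_id`, `pdb_a`, `pdb_b`,
#'   `mutation`, `ddg_ab`, `ddg_ba`, `exclude` (`""`, `"proline"` or
#'   `"server_failure"`).
#' @export
synthetic_selfconsistency_table <- function(n_pairs = 65L, n_proline = 3L,
                                            n_failures = 5L,
                                            antisym_noise = 0.3,
                                            seed = 1L) {
  if (n_proline + n_failures > n_pairs)
    stop("more exclusions than pairs")
  .with_seed(seed, {
    fwd <- stats::rnorm(n_pairs, 0.5, 1.2)
    bwd <- -fwd + stats::rnorm(n_pairs, 0, antisym_noise)
    exclude <- rep("", n_pairs)
    flagged <- sample.int(n_pairs, n_proline + n_failures)
    exclude[flagged[seq_len(n_proline)]] <- "proline"
    exclude[flagged[n_proline + seq_len(n_failures)]] <- "server_failure"
    data.frame(
      pair_id = sprintf("PAIR%03d", seq_len(n_pairs)),
      pdb_a = sprintf("SYA%02d", seq_len(n_pairs)),
      pdb_b = sprintf("SYB%02d", seq_len(n_pairs)),
      mutation = paste0(sample(.aa1, n_pairs, TRUE),
                        sample.int(120L, n_pairs, TRUE),
                        sample(.aa1, n_pairs, TRUE)),
      ddg_ab = fwd, ddg_ba = bwd, exclude = exclude,
      stringsAsFactors = FALSE)
  })
}

#' Apply the exclusion list of a self-consistency table
#'
#' Drops rows with a nonempty `exclude` flag (the evaluator takes an
#' explicit exclusion column rather than hard-coding cases).
#'
#' @param tab Table from [synthetic_selfconsistency_table()] (or any table
#'   with an `exclude` column).
#' @return The filtered table.
#' @export
apply_exclusions <- function(tab) {
  if (is.null(tab$exclude)) return(tab)
  out <- tab[tab$exclude == "", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic paired-conformation benchmark manifest
#'
#' Entries of a conformational-change benchmark: one row per apo/holo
#' structure pair, classified by motion type (`domain`/`loop`) and coupling
#' to ligand binding (`independent`/`coupled`).  The default composition
#' matches the analysed published subset: 124 domain pairs (65 independent
#' + 59 coupled) and 244 loop pairs (126 independent + 118 coupled), i.e.
#' 368 pairs and 736 directed changes after [expand_directed()].
#'
#' @param domain_independent,domain_coupled,loop_independent,loop_coupled
#'   Pair counts per category.
#' @return A data frame with columns `entry_id`, `motion`, `coupling`,
#'   `pdb_apo`, `pdb_holo`.
#' @export
synthetic_overlap_manifest <- function(domain_independent = 65L,
                                       domain_coupled = 59L,
                                       loop_independent = 126L,
                                       loop_coupled = 118L) {
  motion <- c(rep("domain", domain_independent + domain_coupled),
              rep("loop", loop_independent + loop_coupled))
  coupling <- c(rep("independent", domain_independent),
                rep("coupled", domain_coupled),
                rep("independent", loop_independent),
                rep("coupled", loop_coupled))
  n <- length(motion)
  data.frame(entry_id = sprintf("ENTRY%03d", seq_len(n)),
             motion = motion, coupling = coupling,
             pdb_apo = sprintf("APO%03d", seq_len(n)),
             pdb_holo = sprintf("HOL%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Expand a pair manifest into directed conformational changes
#'
#' Each apo/holo pair yields two directed tasks: apo to holo and holo to
#' apo.
#'
#' @param manifest Table from [synthetic_overlap_manifest()].
#' @return A data frame with one row per directed change and a `direction`
#'   column (`"apo_to_holo"`/`"holo_to_apo"`).
#' @export
expand_directed <- function(manifest) {
  fwd <- manifest
  fwd$direction <- "apo_to_holo"
  fwd$start <- manifest$pdb_apo
  fwd$target <- manifest$pdb_holo
  bwd <- manifest
  bwd$direction <- "holo_to_apo"
  bwd$start <- manifest$pdb_holo
  bwd$target <- manifest$pdb_apo
  out <- rbind(fwd, bwd)
  rownames(out) <- NULL
  out
}
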