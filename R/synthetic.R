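# Synthetic fixtures: download-free inputs with the structure the pipeline
# assumes — confined self-avoiding CA walks written as PDB, random
# amino-acid sequences, and labeled pairs with a planted, learnable
# interaction signal.
#
# Each protein carries a scalar latent "interaction propensity" u drawn
# from N(0, 1). The latent tilts the residue composition (so AC/CT and the
# attribute voxel channels reflect it) and the backbone stiffness (so the
# occupancy channel reflects it); a pair is labeled interacting when the
# summed propensity u_a + u_b exceeds a threshold chosen to hit the
# requested positive fraction, with a small label-noise rate.

#' Synthetic dataset configuration
#'
#' @param n_proteins number of proteins to generate
#' @param residues_range (min, max) residue counts; the minimum must be at
#'   least 50, matching the usual short-protein exclusion in PPI
#'   benchmarks
#' @param n_pairs number of labeled pairs (distinct unordered pairs)
#' @param positive_fraction target fraction of interacting pairs
#' @param signal_strength how strongly the latent propensity tilts
#'   composition and backbone stiffness; 0 removes all signal
#' @param label_noise probability of flipping each planted label
#' @param seed master seed; the whole fixture set is reproducible from it
#' @return a `synth_config` list
#' @export
synth_config <- function(n_proteins = 80, residues_range = c(50, 150),
                         n_pairs = 600, positive_fraction = 0.5,
                         signal_strength = 2, label_noise = 0.01,
                         seed = 1) {
  if (residues_range[1] < 50) {
    vox_abort("config", "minimum residue length is 50")
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    vox_abort("config", "`positive_fraction` must be in (0, 1)")
  }
  if (signal_strength < 0) {
    vox_abort("config", "`signal_strength` must be >= 0")
  }
  structure(list(n_proteins = n_proteins,
                 residues_range = residues_range, n_pairs = n_pairs,
                 positive_fraction = positive_fraction,
                 signal_strength = signal_strength,
                 label_noise = label_noise, seed = seed),
            class = "synth_config")
}

# composition tilt direction over the 20 amino acids: hydropathy scaled
# to +-1, so exp(strength * u * tilt) shifts hydrophobic content with u
aa_tilt <- function() {
  kd <- voxel_attribute_tables()$hydropathy[AA_ALPHABET]
  kd / max(abs(kd))
}

sample_sequence <- function(length, tilt_exponent = 0) {
  w <- AA_BACKGROUND_FREQ[AA_ALPHABET] * exp(tilt_exponent * aa_tilt())
  paste(sample(AA_ALPHABET, length, replace = TRUE, prob = w / sum(w)),
        collapse = "")
}

#' Generate random protein sequences
#'
#' i.i.d. draws over the 20 standard amino acids at background
#' frequencies, reproducible per seed.
#'
#' @param n number of sequences
#' @param length_range (min, max) sequence lengths, minimum 50
#' @param seed RNG seed
#' @return tibble with columns `id` and `seq`
#' @export
synth_sequences <- function(n, length_range = c(50, 150), seed = 1) {
  if (length_range[1] < 50) {
    vox_abort("config", "minimum sequence length is 50")
  }
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    tibble(id = sprintf("prot%03d", seq_len(n)),
           seq = vapply(lens, sample_sequence, ""))
  })
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic backbone trace
#'
#' A persistent self-avoiding random walk of alpha-carbons with
#' consecutive spacing 3.8 +- 0.1 Angstrom, confined to a ball so that
#' after recentring every atom lies well inside a 40-Angstrom radius;
#' amide N and carbonyl C atoms are placed at bonded distances around each
#' CA. Higher `signal_strength * latent` makes the walk stiffer (more
#' extended).
#'
#' @param n_residues number of residues (>= 2)
#' @param seed RNG seed
#' @param sequence optional 1-letter sequence of length `n_residues`;
#'   defaults to background-frequency draws
#' @param latent latent propensity entering the stiffness (default 0)
#' @param signal_strength stiffness coupling (default 0)
#' @return list with `trace` (a `backbone_trace` of 3 atoms per residue)
#'   and `pdb_text` (character vector of PDB lines)
#' @export
synth_backbone <- function(n_residues, seed = 1, sequence = NULL,
                           latent = 0, signal_strength = 0) {
  n_residues <- stopifnot_scalar_int(n_residues, "n_residues")
  if (n_residues < 2) vox_abort("config", "`n_residues` must be >= 2")
  if (!is.null(sequence)) {
    chars <- check_sequence(sequence)
    if (length(chars) != n_residues) {
      vox_abort("config", "sequence length must equal n_residues")
    }
  }
  with_seed(seed, {
    if (is.null(sequence)) {
      chars <- sample(AA_ALPHABET, n_residues, replace = TRUE,
                      prob = AA_BACKGROUND_FREQ[AA_ALPHABET])
    }
    r_conf <- 18                       # confinement radius, Angstrom
    kappa <- 0.2 + 0.6 * stats::plogis(signal_strength * latent)
    ca <- matrix(0, n_residues, 3)
    dir <- rand_unit()
    for (i in 2:n_residues) {
      placed <- FALSE
      for (try in 1:300) {
        # persistent proposal first; fall back to an unbiased direction
        # when the stiff direction keeps failing near the boundary
        prop_dir <- if (try <= 50) {
          kappa * dir + (1 - kappa) * rand_unit()
        } else {
          rand_unit()
        }
        prop_dir <- prop_dir / sqrt(sum(prop_dir^2))
        step <- runif(1, 3.7, 3.9)
        cand <- ca[i - 1, ] + step * prop_dir
        # reflect back toward the origin at the confinement boundary
        if (sqrt(sum(cand^2)) > r_conf) {
          prop_dir <- prop_dir - 2 * sum(prop_dir * cand) * cand /
            sum(cand^2)
          prop_dir <- prop_dir / sqrt(sum(prop_dir^2))
          cand <- ca[i - 1, ] + step * prop_dir
        }
        d2 <- rowSums((ca[seq_len(i - 1), , drop = FALSE] -
                         matrix(cand, i - 1, 3, byrow = TRUE))^2)
        if (all(d2 > 4) && sqrt(sum(cand^2)) <= r_conf) {
          ca[i, ] <- cand
          dir <- prop_dir
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        vox_abort("generation",
                  sprintf("self-avoiding walk stuck at residue %d", i))
      }
    }
    ca <- sweep(ca, 2, colMeans(ca))   # centre on the centroid

    rows <- vector("list", n_residues)
    for (i in seq_len(n_residues)) {
      n_atom <- ca[i, ] + 1.45 * rand_unit()
      c_atom <- ca[i, ] + 1.52 * rand_unit()
      res3 <- unname(AA_ONE_TO_THREE[chars[i]])
      rows[[i]] <- tibble(
        atom_name = c("N", "CA", "C"),
        residue_name = res3,
        residue_index = i,
        chain_id = "A",
        x = c(n_atom[1], ca[i, 1], c_atom[1]),
        y = c(n_atom[2], ca[i, 2], c_atom[2]),
        z = c(n_atom[3], ca[i, 3], c_atom[3])
      )
    }
    trace <- dplyr::bind_rows(rows)
    trace$residue_1 <- unname(AA_THREE_TO_ONE[trace$residue_name])
    trace <- new_backbone_trace(trace)
    list(trace = trace, pdb_text = write_pdb_backbone(trace))
  })
}

#' Generate a labeled synthetic PPI dataset
#'
#' Draws a latent propensity per protein, generates sequences and backbone
#' traces that both carry the latent (composition tilt and walk
#' stiffness), samples distinct protein pairs, and labels a pair positive
#' when the summed propensity exceeds the threshold that realizes the
#' requested positive fraction; labels are then flipped at the configured
#' noise rate.
#'
#' @param cfg a [synth_config()]
#' @return a `synth_ppi` list: `proteins` (tibble with `id`, `seq`,
#'   `latent`, `n_residues` and a `trace` list-column), `pairs` (tibble
#'   `id_a`, `id_b`, `label`) and `rule` (latents, similarity, threshold,
#'   noise rate, seed)
#' @export
#' @examples
#' ds <- synth_ppi_dataset(synth_config(n_proteins = 12, n_pairs = 30,
#'                                      seed = 1))
#' table(ds$pairs$label)
synth_ppi_dataset <- function(cfg = synth_config()) {
  n <- cfg$n_proteins
  max_pairs <- choose(n, 2)
  if (cfg$n_pairs > max_pairs) {
    vox_abort("generation",
              sprintf("%d pairs requested but only %d distinct pairs exist",
                      cfg$n_pairs, max_pairs))
  }
  u <- with_seed(child_seed(cfg$seed, 10), rnorm(n))
  ids <- sprintf("prot%03d", seq_len(n))

  lens <- with_seed(child_seed(cfg$seed, 11),
                    sample(cfg$residues_range[1]:cfg$residues_range[2], n,
                           replace = TRUE))
  seqs <- vapply(seq_len(n), function(i) {
    with_seed(child_seed(cfg$seed, 100 + i),
              sample_sequence(lens[i], cfg$signal_strength * u[i]))
  }, "")

  traces <- lapply(seq_len(n), function(i) {
    synth_backbone(lens[i], seed = child_seed(cfg$seed, 10000 + i),
                   sequence = seqs[i], latent = u[i],
                   signal_strength = cfg$signal_strength)$trace
  })

  pairs <- with_seed(child_seed(cfg$seed, 12), {
    pick <- sample.int(max_pairs, cfg$n_pairs)
    all_pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    tibble(a = all_pairs[pick, 1], b = all_pairs[pick, 2])
  })
  s <- u[pairs$a] + u[pairs$b]
  n_pos <- round(cfg$positive_fraction * cfg$n_pairs)
  ord <- order(s, decreasing = TRUE)
  label <- integer(cfg$n_pairs)
  label[ord[seq_len(n_pos)]] <- 1L
  threshold <- mean(s[ord[n_pos + c(0, 1)]])
  flip <- with_seed(child_seed(cfg$seed, 13),
                    runif(cfg$n_pairs) < cfg$label_noise)
  label_noisy <- ifelse(flip, 1L - label, label)

  structure(list(
    proteins = tibble(id = ids, seq = seqs, latent = u,
                      n_residues = lens, trace = traces),
    pairs = tibble(id_a = ids[pairs$a], id_b = ids[pairs$b],
                   label = label_noisy),
    rule = list(latent = setNames(u, ids), similarity = "propensity_sum",
                threshold = threshold, label_noise = cfg$label_noise,
                seed = cfg$seed),
    config = cfg
  ), class = "synth_ppi")
}

#' Write a synthetic dataset to a fixture directory
#'
#' Produces `structures/<id>.pdb`, `sequences.fasta`, `pairs.tsv` and
#' `rule.json`, all consumable by the package's readers.
#'
#' @param ds a `synth_ppi` from [synth_ppi_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture_dir <- function(ds, dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_len(nrow(ds$proteins))) {
    write_pdb_backbone(ds$proteins$trace[[i]],
                       file.path(dir, "structures",
                                 paste0(ds$proteins$id[i], ".pdb")))
  }
  write_fasta(ds$proteins, file.path(dir, "sequences.fasta"))
  write_pairs(ds$pairs, file.path(dir, "pairs.tsv"))
  writeLines(jsonlite::toJSON(ds$rule, auto_unbox = TRUE, digits = NA),
             file.path(dir, "rule.json"))
  invisible(dir)
}
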