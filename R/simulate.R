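# Synthetic orthologous-group generator: motif-bearing families with variable
# lengths and imbalanced populations, providing ground truth for end-to-end
# tests without any external database.

# sample() without the scalar-x surprise (sample(5, 1) draws from 1:5)
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Draw specifications for a set of synthetic protein families
#'
#' Each family (orthologous group) is defined by a set of motif consensus
#' sequences implanted at fixed relative positions, a uniform length law and a
#' population size. Populations follow a power law over the family rank,
#' `round(base_population * r^(-imbalance_exponent))` with a floor of 1, so
#' that `imbalance_exponent = 0` gives balanced groups and larger exponents
#' emulate the heavily skewed group populations of real orthology databases
#' (down to singletons).
#'
#' @param n_groups Number of families.
#' @param motifs_per_group Motifs implanted per family (default 3).
#' @param imbalance_exponent Power-law exponent >= 0 (default 0 = balanced).
#' @param base_population Population of the first-ranked family (default 100).
#' @param length_range Integer (min, max) for uniform sequence lengths.
#' @param motif_length_range Integer (min, max) for uniform motif consensus
#'   lengths (default 6--12).
#' @param mutation_prob Per-site substitution probability applied to implanted
#'   motifs (default 0.05). Substituted sites redraw uniformly over the 20
#'   standard residues and may silently retain the original residue.
#' @param seed Integer seed; identical seeds yield identical specs.
#' @param prefix Group-id prefix (default `"SOG"`); use a different prefix to
#'   generate out-model families whose ids are disjoint from a trained model.
#' @return Tibble of class `og_family_specs` with columns `group_id`,
#'   `population`, `length_min`, `length_max` and a `motifs` list-column of
#'   tibbles (`consensus`, `relative_position`, `per_site_mutation_prob`).
#' @examples
#' specs <- family_specs(3, imbalance_exponent = 1, base_population = 100, seed = 1)
#' specs$population  # 100 50 33
#' @export
family_specs <- function(n_groups, motifs_per_group = 3L,
                         imbalance_exponent = 0, base_population = 100L,
                         length_range = c(80L, 300L),
                         motif_length_range = c(6L, 12L),
                         mutation_prob = 0.05, seed = 1L, prefix = "SOG") {
  stopifnot(n_groups >= 1, imbalance_exponent >= 0, base_population >= 1,
            motifs_per_group >= 0, mutation_prob >= 0, mutation_prob <= 1)
  if (length_range[1] < motif_length_range[2]) {
    stop(sprintf(
      "minimum sequence length %d is shorter than the longest possible motif (%d)",
      length_range[1], motif_length_range[2]))
  }
  pop <- pmax(round(base_population * seq_len(n_groups)^(-imbalance_exponent)), 1)
  with_seed(seed, {
    motifs <- lapply(seq_len(n_groups), function(g) {
      lens <- resample(seq(motif_length_range[1], motif_length_range[2]),
                       motifs_per_group, replace = TRUE)
      tibble::tibble(
        consensus = vapply(lens, function(l) {
          paste(sample(std_residues(), l, replace = TRUE), collapse = "")
        }, character(1)),
        relative_position = stats::runif(motifs_per_group),
        per_site_mutation_prob = rep(mutation_prob, motifs_per_group)
      )
    })
    out <- tibble::tibble(
      group_id = sprintf("%s%04d", prefix, seq_len(n_groups)),
      population = as.integer(pop),
      length_min = as.integer(length_range[1]),
      length_max = as.integer(length_range[2]),
      motifs = motifs
    )
    class(out) <- c("og_family_specs", class(out))
    out
  })
}

#' Sample one sequence from a family specification
#'
#' Background residues are i.i.d. uniform over the 20 standard amino acids;
#' each motif is implanted at `floor(relative_position * (L - |consensus|))`
#' (0-based) in listed order, so later motifs overwrite earlier ones on
#' overlap. Each motif site is independently substituted with probability
#' `per_site_mutation_prob` by a uniform draw over the 20 standard residues
#' (which may redraw the original residue). Uses the current RNG state.
#'
#' @param family One row of an `og_family_specs` tibble (or an equivalent
#'   list with `length_min`, `length_max`, `motifs`).
#' @return Character scalar: the sampled residue sequence.
#' @export
sample_sequence <- function(family) {
  if (is.data.frame(family)) family <- as.list(family[1, ])
  motifs <- family$motifs
  if (is.list(motifs) && !is.data.frame(motifs)) motifs <- motifs[[1]]
  L <- resample(seq(family$length_min, family$length_max), 1L)
  res <- sample(std_residues(), L, replace = TRUE)
  if (!is.null(motifs) && nrow(motifs) > 0) {
    for (m in seq_len(nrow(motifs))) {
      cons <- strsplit(motifs$consensus[m], "")[[1]]
      k <- length(cons)
      start <- floor(motifs$relative_position[m] * (L - k)) + 1L
      site <- cons
      mut <- stats::runif(k) < motifs$per_site_mutation_prob[m]
      if (any(mut)) site[mut] <- sample(std_residues(), sum(mut), replace = TRUE)
      res[start:(start + k - 1L)] <- site
    }
  }
  paste(res, collapse = "")
}

#' Simulate all sequences for a set of family specifications
#'
#' @param specs An `og_family_specs` tibble from [family_specs()].
#' @param seed Integer seed; identical (specs, seed) yield identical output.
#' @return Tibble with columns `id`, `description`, `sequence`, `group`.
#' @export
simulate_sequences <- function(specs, seed = 1L) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(specs)), function(g) {
      fam <- specs[g, ]
      seqs <- vapply(seq_len(fam$population), function(i) sample_sequence(fam),
                     character(1))
      tibble::tibble(
        id = sprintf("%s_%05d", fam$group_id, seq_len(fam$population)),
        description = sprintf("synthetic member of %s", fam$group_id),
        sequence = seqs,
        group = fam$group_id
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a synthetic orthologous-group dataset on disk
#'
#' Writes a FASTA file and a two-column label table; output is byte-identical
#' for identical (specs, seed).
#'
#' @param specs An `og_family_specs` tibble.
#' @param out_fasta,out_labels Output paths.
#' @param seed Integer seed.
#' @param out_manifest Optional path for a JSON manifest.
#' @return The dataset manifest (class `og_manifest`): seed, per-family totals
#'   and the record count.
#' @export
generate_dataset <- function(specs, out_fasta, out_labels, seed = 1L,
                             out_manifest = NULL) {
  records <- simulate_sequences(specs, seed = seed)
  write_fasta(records, out_fasta)
  write_labels(records[, c("id", "group")], out_labels)
  totals <- dplyr::count(records, .data$group, name = "n")
  manifest <- structure(
    list(seed = as.integer(seed), n_groups = nrow(specs),
         totals = totals, n_records = nrow(records)),
    class = "og_manifest"
  )
  if (!is.null(out_manifest)) {
    jsonlite::write_json(
      list(seed = manifest$seed, n_groups = manifest$n_groups,
           n_records = manifest$n_records,
           totals = as.data.frame(totals)),
      out_manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  manifest
}

#' @export
print.og_manifest <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d sequences in %d groups (seed %d)\n",
              x$n_records, x$n_groups, x$seed))
  invisible(x)
}
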