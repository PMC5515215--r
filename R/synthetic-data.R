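# Seeded generators for every input the pipeline consumes, each paired with a
# ground-truth record so downstream stages can be tested against known answers.

#' The universal V6 primer used for tag profiling
#'
#' The degenerate universal primer targeting the 16S rRNA hypervariable
#' region V6; the 33 nucleotides immediately downstream of a primer match
#' define the V6 tag used as a taxon proxy.
#'
#' @return The primer as a single IUPAC string (19 nt).
#' @export
v6_primer <- function() "CGACRRCCATGCANCACCT"

# Fixed flanking context placed before the primer site in simulated reads.
read_flank_context <- function(n) {
  if (n <= 0) return("")
  paste(rep_len(c("T", "A", "G", "C"), n), collapse = "")
}

#' Simulate 16S V6 amplicon-bearing sequencing reads with ground truth
#'
#' Generates single-end reads that each carry the V6 primer site (degenerate
#' positions concretised uniformly at random per read), followed by a planted
#' 33-nt tag subject to a per-base substitution error rate, followed by random
#' bases to the read length. A fixed flanking context precedes the primer.
#' Errors are applied across the entire read, so they can also disrupt the
#' primer site.
#'
#' The returned truth table applies the two literal tag filters (kept iff
#' total supporting reads >= `min_reads` and the most common full-read
#' sequence accounts for < `max_type_fraction` of them) to the reads that
#' still carry an intact primer site and an unmutated tag, giving the
#' expected post-filter outcome per planted tag.
#'
#' @param plans Data frame with one row per planted taxon: columns
#'   `taxon_id`, `tag_sequence` (33-nt DNA), `n_reads`; optional
#'   `per_base_error_rate` (default 0), `read_length` (default 75) and
#'   `primer_offset` (1-based position of the primer start, default 6).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param primer IUPAC primer string, default [v6_primer()].
#' @param min_reads,max_type_fraction Filter thresholds mirrored into the
#'   truth table (defaults 2 and 0.5, the profiling defaults).
#' @return A list with `reads`, a tibble (`read_id`, `sequence`, `quality`)
#'   where quality is a constant Q30 Sanger string, and `truth`, a tibble per
#'   plan with `n_supporting`, `n_read_types`, `max_type_fraction`,
#'   `expect_kept` and `removal_reason`.
#' @examples
#' plan <- tibble::tibble(
#'   taxon_id = "tA",
#'   tag_sequence = paste(rep("ACG", 11), collapse = ""),
#'   n_reads = 5
#' )
#' sim <- gen_reads(plan, seed = 1)
#' sim$truth
#' @export
gen_reads <- function(plans, seed, primer = v6_primer(),
                      min_reads = 2, max_type_fraction = 0.5) {
  plans <- as_tibble(plans)
  if (nrow(plans) == 0) abort("`plans` must contain at least one row")
  assert_columns(plans, c("taxon_id", "tag_sequence", "n_reads"), "plans")
  if (!"per_base_error_rate" %in% names(plans)) plans$per_base_error_rate <- 0
  if (!"read_length" %in% names(plans)) plans$read_length <- 75L
  if (!"primer_offset" %in% names(plans)) plans$primer_offset <- 6L
  if (!is_valid_iupac(primer)) abort("`primer` is not a valid IUPAC string")

  plen <- nchar(primer)
  for (i in seq_len(nrow(plans))) {
    tag <- plans$tag_sequence[[i]]
    if (nchar(tag) != 33 || !is_valid_dna(tag, allow_n = FALSE)) {
      abort(sprintf("tag for taxon '%s' must be a 33-nt ACGT string",
                    plans$taxon_id[[i]]))
    }
    e <- plans$per_base_error_rate[[i]]
    if (!is.finite(e) || e < 0 || e >= 0.5) {
      abort("`per_base_error_rate` must lie in [0, 0.5)")
    }
    if (plans$read_length[[i]] < plans$primer_offset[[i]] - 1 + plen + 33) {
      abort("`read_length` too short to carry primer site plus 33-nt tag")
    }
  }

  iupac <- iupac_table()
  primer_chars <- strsplit(primer, "")[[1]]

  withr::with_seed(as.integer(seed), {
    all_reads <- vector("list", nrow(plans))
    truth <- vector("list", nrow(plans))
    for (i in seq_len(nrow(plans))) {
      nr <- plans$n_reads[[i]]
      rl <- plans$read_length[[i]]
      off <- plans$primer_offset[[i]]
      err <- plans$per_base_error_rate[[i]]
      tag_chars <- strsplit(plans$tag_sequence[[i]], "")[[1]]
      flank <- strsplit(read_flank_context(off - 1), "")[[1]]

      seqs <- character(nr)
      supports <- logical(nr)
      for (r in seq_len(nr)) {
        concrete <- vapply(primer_chars, function(ch) {
          opts <- iupac[[ch]]
          if (length(opts) == 1) opts else sample(opts, 1)
        }, character(1), USE.NAMES = FALSE)
        tail_n <- rl - (off - 1) - plen - 33
        tail_bases <- sample(c("A", "C", "G", "T"), tail_n, replace = TRUE)
        base <- c(flank, concrete, tag_chars, tail_bases)
        mutated <- base
        if (err > 0) {
          hit <- runif(rl) < err
          for (pos in which(hit)) {
            mutated[pos] <- sample(setdiff(c("A", "C", "G", "T"), base[pos]), 1)
          }
        }
        # A read supports its planted tag iff the (possibly mutated) primer
        # region still matches the IUPAC primer and the tag is unmutated.
        prim_region <- mutated[off:(off + plen - 1)]
        prim_ok <- all(vapply(seq_len(plen), function(j) {
          prim_region[j] %in% iupac[[primer_chars[j]]]
        }, logical(1)))
        tag_ok <- identical(mutated[(off + plen):(off + plen + 32)], tag_chars)
        supports[r] <- prim_ok && tag_ok
        seqs[r] <- paste(mutated, collapse = "")
      }
      all_reads[[i]] <- tibble(
        read_id = sprintf("%s_read%04d", plans$taxon_id[[i]], seq_len(nr)),
        sequence = seqs,
        quality = strrep("?", rl)  # constant Q30 (Sanger encoding)
      )

      sup_seqs <- seqs[supports]
      n_sup <- length(sup_seqs)
      type_counts <- if (n_sup > 0) table(sup_seqs) else integer(0)
      max_frac <- if (n_sup > 0) max(type_counts) / n_sup else NA_real_
      kept <- n_sup >= min_reads && !is.na(max_frac) && max_frac < max_type_fraction
      reason <- if (kept) {
        NA_character_
      } else if (n_sup < min_reads) {
        sprintf("removed by >=%d-read filter", min_reads)
      } else {
        sprintf("removed by >=%d%% single-read-type filter",
                round(100 * max_type_fraction))
      }
      truth[[i]] <- tibble(
        taxon_id = plans$taxon_id[[i]],
        tag_sequence = plans$tag_sequence[[i]],
        n_reads_planted = nr,
        n_supporting = n_sup,
        n_read_types = length(type_counts),
        max_type_fraction = max_frac,
        expect_kept = kept,
        removal_reason = reason
      )
    }
    list(reads = bind_rows(all_reads), truth = bind_rows(truth))
  })
}

#' Write simulated reads as FASTQ / read sequencing reads into a tibble
#'
#' Thin wrappers around Biostrings for plain or gzipped FASTQ/FASTA.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `quality`.
#' @param path File path.
#' @return `write_reads_fastq()` returns `path` invisibly; `read_reads()`
#'   returns a tibble with `read_id`, `sequence` and (for FASTQ) `quality`.
#' @export
write_reads_fastq <- function(reads, path) {
  assert_columns(reads, c("read_id", "sequence"), "reads")
  withCallingHandlers(
    {
      qual <- reads$quality %||% strrep("?", nchar(reads$sequence))
      x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(reads$sequence),
        Biostrings::PhredQuality(qual)
      )
      names(x) <- reads$read_id
      Biostrings::writeQualityScaledXStringSet(x, path)
    },
    # QualityScaled sets carry their qualities as metadata columns; the
    # FASTQ writer re-creates them and warns about the (irrelevant) drop.
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  invisible(path)
}

#' @rdname write_reads_fastq
#' @param format `"fastq"` or `"fasta"`.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "fastq") {
    # the reader stores qualities as metadata columns and warns when the
    # plain character view drops them; that drop is intended here
    withCallingHandlers(
      {
        x <- Biostrings::readQualityScaledDNAStringSet(path)
        tibble(
          read_id = sub("\\s.*$", "", names(x)),
          sequence = unname(as.character(x)),
          quality = unname(as.character(Biostrings::quality(x)))
        )
      },
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    tibble(
      read_id = sub("\\s.*$", "", names(x)),
      sequence = unname(as.character(x))
    )
  }
}

#' Simulate an AHL spiking time course with its two controls
#'
#' Emulates a signal-inactivation microcosm experiment: a synthetic AHL is
#' spiked at `c0` (default 5 uM) into live sludge, heat-inactivated sludge
#' and a sterile synthetic-wastewater (SWW) control, and the residual
#' concentration is followed over time.
#'
#' * `sww_control`: no biomass; abiotic loss is negligible at pH <= 8.3, so
#'   the series stays at `c0` (up to noise).
#' * `heat_inactivated`: an instantaneous adsorptive drop of
#'   `adsorption_fraction` but no enzymatic decay.
#' * `live`: the adsorptive drop plus zero- or first-order enzymatic decay
#'   with rate constant `rate_constant`.
#'
#' Noise is multiplicative lognormal with unit mean and coefficient of
#' variation `noise_cv`; concentrations are truncated at zero.
#'
#' @param ahl AHL acronym, e.g. `"C6-HSL"`.
#' @param order Kinetic order of the live decay, 0 or 1.
#' @param rate_constant Decay rate, uM/h for order 0 or 1/h for order 1 (> 0).
#' @param c0 Spiked concentration in uM (default 5).
#' @param adsorption_fraction Fraction lost instantly to biomass adsorption,
#'   in `[0, 1)` (default 0.2, within the 10-30% typically observed).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param timepoints Sampling times in hours, ascending and starting at 0.
#' @param seed Integer seed.
#' @return A tibble with columns `ahl`, `condition`
#'   (`live`/`heat_inactivated`/`sww_control`), `time_h`, `concentration`.
#' @examples
#' gen_decay("C6-HSL", order = 1, rate_constant = log(2) / 1.95,
#'           noise_cv = 0, timepoints = 0:6, seed = 1)
#' @export
gen_decay <- function(ahl, order, rate_constant, c0 = 5,
                      adsorption_fraction = 0.2, noise_cv = 0.1,
                      timepoints = seq(0, 6, length.out = 8), seed = 1) {
  if (length(timepoints) == 0) abort("`timepoints` must be non-empty")
  if (timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE)) {
    abort("`timepoints` must be strictly ascending and start at 0")
  }
  if (!order %in% c(0, 1)) abort("`order` must be 0 or 1")
  assert_number(rate_constant, "rate_constant", lower = 0, strict_lower = TRUE)
  assert_number(c0, "c0", lower = 0, strict_lower = TRUE)
  assert_number(adsorption_fraction, "adsorption_fraction",
                lower = 0, upper = 1, strict_upper = TRUE)
  assert_number(noise_cv, "noise_cv", lower = 0)

  t <- as.numeric(timepoints)
  post_ads <- (1 - adsorption_fraction) * c0
  mean_curves <- list(
    sww_control = rep(c0, length(t)),
    heat_inactivated = rep(post_ads, length(t)),
    live = if (order == 1) {
      post_ads * exp(-rate_constant * t)
    } else {
      pmax(0, post_ads - rate_constant * t)
    }
  )
  withr::with_seed(as.integer(seed), {
    purrr::imap(mean_curves, function(mu, cond) {
      tibble(
        ahl = ahl, condition = cond, time_h = t,
        concentration = pmax(0, mu * lognormal_factor(length(t), noise_cv))
      )
    }) |> bind_rows()
  })
}

#' Simulate a matrix-matched calibration table
#'
#' Generates peak areas for standards spanning the working range of a
#' matrix-matched calibration (default 0.5-200 ug/l):
#' `area = intercept + slope * level + N(0, noise_sd)`.
#'
#' @param slope Area units per ug/l (> 0).
#' @param intercept Baseline area.
#' @param noise_sd Additive Gaussian noise SD on areas.
#' @param levels Standard concentrations in ug/l, each within `[0.5, 200]`.
#' @param seed Integer seed.
#' @return A tibble with `level_ugL` and `area`.
#' @export
gen_calibration <- function(slope, intercept = 0, noise_sd = 0,
                            levels = c(0.5, 1, 2, 5, 10, 20, 50, 100, 200),
                            seed = 1) {
  assert_number(slope, "slope", lower = 0, strict_lower = TRUE)
  assert_number(noise_sd, "noise_sd", lower = 0)
  if (any(levels < 0.5 | levels > 200)) {
    abort("`levels` must lie within the 0.5-200 ug/l calibration range")
  }
  withr::with_seed(as.integer(seed), {
    tibble(
      level_ugL = as.numeric(levels),
      area = intercept + slope * levels + rnorm(length(levels), 0, noise_sd)
    )
  })
}

#' Simulate taxa-abundance and AHL-concentration time series with planted
#' correlations
#'
#' Emulates the joint profiling of community member abundances and in-situ
#' AHL concentrations over time. Each AHL concentration series is driven by
#' an independent standard-normal latent series `z`. A taxon with planted
#' sign `s` (+1/-1) on an AHL follows
#' `x = s * effect_size * z + sqrt(1 - effect_size^2) * noise_sd * epsilon`,
#' so at the default `noise_sd = 1` the population Pearson correlation is
#' exactly `s * effect_size`; taxa with sign 0 everywhere are independent
#' noise. Latent series are mapped affinely to positive abundance and
#' concentration scales (Pearson correlation is unaffected).
#'
#' A taxon may be planted against at most one AHL (rows of
#' `planted_sign_matrix` with several nonzero entries are rejected), keeping
#' the planted correlation structure exactly realisable.
#'
#' @param n_taxa,n_timepoints,n_ahls Dimensions; `n_timepoints` must be >= 3.
#' @param planted_sign_matrix `n_taxa x n_ahls` matrix over `{-1, 0, 1}`;
#'   default all zero.
#' @param effect_size Target absolute Pearson correlation in `(0, 1]`.
#' @param noise_sd Residual dispersion multiplier (default 1).
#' @param seed Integer seed.
#' @return A list with `taxa` (tibble `taxon`, `timepoint`, `abundance`),
#'   `ahls` (tibble `ahl`, `timepoint`, `concentration`) and `truth`
#'   (tibble `taxon`, `ahl`, `sign`).
#' @export
gen_community_series <- function(n_taxa, n_timepoints, n_ahls,
                                 planted_sign_matrix = NULL,
                                 effect_size = 0.9, noise_sd = 1, seed = 1) {
  if (n_timepoints < 3) abort("`n_timepoints` must be at least 3")
  assert_number(effect_size, "effect_size", lower = 0, upper = 1,
                strict_lower = TRUE)
  assert_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(planted_sign_matrix)) {
    planted_sign_matrix <- matrix(0, n_taxa, n_ahls)
  }
  planted_sign_matrix <- as.matrix(planted_sign_matrix)
  if (!all(dim(planted_sign_matrix) == c(n_taxa, n_ahls))) {
    abort("`planted_sign_matrix` must be n_taxa x n_ahls")
  }
  if (!all(planted_sign_matrix %in% c(-1, 0, 1))) {
    abort("`planted_sign_matrix` entries must be -1, 0 or +1")
  }
  if (any(rowSums(planted_sign_matrix != 0) > 1)) {
    abort("each taxon may be planted against at most one AHL")
  }

  taxa_names <- sprintf("Tag%02d", seq_len(n_taxa))
  ahl_names <- sprintf("AHL%02d", seq_len(n_ahls))
  withr::with_seed(as.integer(seed), {
    z <- matrix(rnorm(n_ahls * n_timepoints), n_ahls, n_timepoints)
    x <- matrix(NA_real_, n_taxa, n_timepoints)
    for (i in seq_len(n_taxa)) {
      j <- which(planted_sign_matrix[i, ] != 0)
      eps <- rnorm(n_timepoints)
      if (length(j) == 1) {
        s <- planted_sign_matrix[i, j]
        x[i, ] <- s * effect_size * z[j, ] +
          sqrt(1 - effect_size^2) * noise_sd * eps
      } else {
        x[i, ] <- eps
      }
    }
    # Affine maps to positive scales; truncation at 0 is a rare tail event.
    abundance <- pmax(0, 10 + x)
    conc <- pmax(0, 50 + 10 * z)
    list(
      taxa = tibble(
        taxon = rep(taxa_names, times = n_timepoints),
        timepoint = rep(seq_len(n_timepoints), each = n_taxa),
        abundance = as.vector(abundance)
      ),
      ahls = tibble(
        ahl = rep(ahl_names, times = n_timepoints),
        timepoint = rep(seq_len(n_timepoints), each = n_ahls),
        concentration = as.vector(conc)
      ),
      truth = tibble(
        taxon = rep(taxa_names, times = n_ahls),
        ahl = rep(ahl_names, each = n_taxa),
        sign = as.vector(planted_sign_matrix)
      )
    )
  })
}

#' Simulate an isolate QS/QQ assay panel with planted categories
#'
#' Emulates the screening of sludge isolates for AHL production (biosensor
#' activation plus LC-MS/MS confirmation) and AHL quenching (residual
#' fraction of 5 uM spikes of 3OC6-HSL, 3OC8-HSL and 3OC12-HSL after 2 h,
#' relative to a pH-matched sterile control). Categories are sampled
#' multinomially from `proportions`.
#'
#' Planted quenchers always degrade the long-chain 3OC12-HSL; a fraction
#' `broad_spectrum` of them (default 0.23) additionally degrades the short-
#' and/or medium-chain AHLs, mirroring the quenching specificity typically
#' seen in floccular sludge.
#'
#' @param n Number of isolates.
#' @param proportions Numeric length-4 vector of category probabilities in
#'   the order producer-only, quencher-only, both, neither; must sum to 1.
#'   The default reproduces the observed floccular-sludge panel distribution
#'   (5.2% producer-only, 53.3% quencher-only, 4.8% both, 36.7% neither).
#' @param broad_spectrum Probability a quencher also degrades short/medium
#'   chains.
#' @param noise_cv Multiplicative noise CV on residual fractions (default 0,
#'   so planted categories round-trip exactly through [classify_isolate()]).
#' @param seed Integer seed.
#' @return A list with `assays`, one row per isolate (biosensor flags,
#'   `produced_ahls` comma string, residual and control fractions for the
#'   three test AHLs, `control_ph`), and `truth` (`isolate_id`,
#'   `category`).
#' @export
gen_isolates <- function(n, proportions = c(0.052, 0.533, 0.048, 0.367),
                         broad_spectrum = 0.23, noise_cv = 0, seed = 1) {
  if (length(proportions) != 4 || abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must be 4 category probabilities summing to 1")
  }
  cats <- c("producer", "quencher", "both", "neither")
  produced_pool <- c("C4-HSL", "C6-HSL", "3OC6-HSL", "C8-HSL", "3OC8-HSL",
                     "C10-HSL", "C12-HSL", "3OC12-HSL", "C14-HSL")
  withr::with_seed(as.integer(seed), {
    category <- sample(cats, n, replace = TRUE, prob = proportions)
    is_prod <- category %in% c("producer", "both")
    is_quench <- category %in% c("quencher", "both")

    produced <- purrr::map_chr(is_prod, function(p) {
      if (!p) return("")
      k <- sample(2:4, 1)  # producers synthesise more than one AHL
      paste(sample(produced_pool, k), collapse = ",")
    })
    control <- 0.95  # slight abiotic loss in the sterile control
    quench_ratio <- 0.10
    res <- matrix(control, n, 3,
                  dimnames = list(NULL, c("res_3OC6", "res_3OC8", "res_3OC12")))
    for (i in which(is_quench)) {
      res[i, "res_3OC12"] <- quench_ratio * control  # all quenchers hit long chain
      if (runif(1) < broad_spectrum) {
        which_sm <- sample(1:3, 1)  # short, medium, or both
        if (which_sm %in% c(1, 3)) res[i, "res_3OC6"] <- quench_ratio * control
        if (which_sm %in% c(2, 3)) res[i, "res_3OC8"] <- quench_ratio * control
      }
    }
    if (noise_cv > 0) {
      res <- res * matrix(lognormal_factor(3 * n, noise_cv), n, 3)
    }
    ids <- sprintf("ISO%04d", seq_len(n))
    assays <- tibble(
      isolate_id = ids,
      taxon = sprintf("Genus%02d", sample(1:50, n, replace = TRUE)),
      a136_positive = is_prod,
      cv026_positive = is_prod & runif(n) < 0.5,
      jba357_positive = is_prod & runif(n) < 0.5,
      produced_ahls = produced,
      residual_3OC6 = res[, "res_3OC6"],
      residual_3OC8 = res[, "res_3OC8"],
      residual_3OC12 = res[, "res_3OC12"],
      control_3OC6 = control,
      control_3OC8 = control,
      control_3OC12 = control,
      control_ph = 7.0
    )
    list(assays = assays, truth = tibble(isolate_id = ids, category = category))
  })
}
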