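# Deterministic synthetic-data generator.
#
# Every generator is a pure function of its sim_config: all randomness
# flows through seeds derived from cfg$seed, and the global RNG state is
# restored on exit. The splicing generator draws random genes, plants a
# motif into a chosen window near a processing site, and samples inclusion
# counts from the same logistic model the inclusion fit assumes; the
# poly(A) generator does the analogous thing for the linear usage model.

#' Simulation configuration
#'
#' Validated bundle of generator settings. Defaults describe the reference
#' perturbation scenario used throughout the package tests: a penta-U
#' repressor active upstream of 3' splice sites in half the samples
#' ("control"), inactive (sign-flipped) in the other half ("knockdown").
#'
#' @param n_exons number of cassette-exon genes (splicing generator).
#' @param n_samples number of samples.
#' @param conditions per-sample condition labels (length `n_samples`).
#' @param motif planted k-mer sequence, or `NULL` for a pure null
#'   simulation.
#' @param activity named per-condition activity `A*` (log-odds units for
#'   splicing, log2 units for poly(A) usage); names must match
#'   `conditions`.
#' @param plant_site site the planting window is anchored at (`"SS3"`,
#'   `"SS5"` or `"PAS"`).
#' @param plant_window half-open sense-offset window `c(start, end)` the
#'   motif is planted into.
#' @param plant_rate probability an event receives one planted site.
#' @param depth binomial total per event and sample (splicing).
#' @param exon_len,flank_exon_len,intron_len gene geometry in nt.
#' @param baseline_sd sd of the per-exon baseline `c_e`.
#' @param b per-sample baseline inclusion log-odds (scalar or vector).
#' @param n_pas_exons,sites_per_exon,pas_spacing,pas_margin poly(A)
#'   generator geometry: number of terminal exons, sites per exon
#'   (sampled uniformly from this set), spacing between tandem sites and
#'   chromosome margin, in nt.
#' @param noise_sd sd of the Gaussian noise on log2 relative usage.
#' @param pas_depth multinomial read depth per exon and sample.
#' @param seed master RNG seed (mandatory; no implicit RNG state).
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_exons = 2000, n_samples = 6,
                       conditions = rep(c("CTRL", "KD"),
                                        length.out = n_samples),
                       motif = "UUUUU",
                       activity = c(CTRL = -2, KD = 2),
                       plant_site = "SS3", plant_window = c(-50, 0),
                       plant_rate = 0.5, depth = 50,
                       exon_len = 80, flank_exon_len = 200,
                       intron_len = 400, baseline_sd = 1, b = 0,
                       n_pas_exons = 300, sites_per_exon = c(2, 3),
                       pas_spacing = 400, pas_margin = 300,
                       noise_sd = 0.25, pas_depth = 1000, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory",
                                           call. = FALSE)
  conditions <- as.character(conditions)
  if (length(conditions) != n_samples) {
    stop("conditions must have length n_samples", call. = FALSE)
  }
  if (!is.null(motif)) {
    motif <- dna_to_rna(motif)
    assert_rna(motif)
    if (!all(unique(conditions) %in% names(activity))) {
      stop("activity must be named by condition", call. = FALSE)
    }
    if (plant_rate < 0 || plant_rate > 1) stop("plant_rate in [0,1]",
                                               call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Named simulation preset
#'
#' `"pentaU_repressor"`: the reference scenario of a penta-U-binding
#' repressor (high in control, depleted in knockdown) acting in the 50 nt
#' upstream of 3' splice sites — 2000 exons, 6 samples (3 CTRL / 3 KD),
#' binomial depth 50, activity -2 in control and +2 in knockdown.
#' `"null"`: no planted motif — 500 exons, 4 samples, used for
#' calibration checks.
#'
#' @param name preset name.
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("pentaU_repressor", "null"), seed, ...) {
  name <- match.arg(name)
  args <- switch(name,
    pentaU_repressor = list(n_exons = 2000, n_samples = 6,
                            conditions = rep(c("CTRL", "KD"), each = 3),
                            motif = "UUUUU",
                            activity = c(CTRL = -2, KD = 2),
                            plant_site = "SS3",
                            plant_window = c(-50, 0), plant_rate = 0.5,
                            depth = 50),
    null = list(n_exons = 500, n_samples = 4,
                conditions = rep(c("A", "B"), each = 2), motif = NULL,
                activity = NULL, plant_rate = 0, depth = 50))
  args$seed <- seed
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

random_rna <- function(n_seqs, len) {
  vapply(seq_len(n_seqs), function(i) {
    paste(sample(RNA_BASES, len, replace = TRUE), collapse = "")
  }, "")
}

#' Simulate a cassette-exon splicing dataset with planted activities
#'
#' Draws one three-exon gene per event (flank, cassette, flank; alternating
#' strands), optionally plants the configured motif into the chosen window
#' near a splice site at the configured rate, computes inclusion
#' probabilities from the logistic model
#' `Theta = logistic(b_s + c_e + Ntilde_e A*_s)` with `N` the realized
#' motif count in the planting window, and draws inclusion evidence
#' `i ~ Binomial(depth, Theta)`. The emitted annotation (inclusion and
#' skipping isoforms) and junction counts round-trip through
#' [select_cassette_exons()].
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `annotation` (`GRanges`),
#'   `junction_counts` (data.frame), `events` (`"cassette_events"`), and
#'   `truth` (per-event planted counts `N`, activities `A`, baselines,
#'   inclusion probabilities `theta`, planting flags).
#' @export
simulate_splicing_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$motif) && cfg$plant_site == "PAS") {
    stop("splicing generator plants at SS3 or SS5", call. = FALSE)
  }
  with_seed(derive_seed(cfg$seed, 1L), {
    E <- cfg$n_exons
    S <- cfg$n_samples
    Fl <- cfg$flank_exon_len
    I <- cfg$intron_len
    X <- cfg$exon_len
    L <- 2 * Fl + 2 * I + X
    ss3_pos <- Fl + I + 1L          # sense position of first exonic base
    ss5_pos <- Fl + I + X           # sense position of last exonic base
    k <- if (is.null(cfg$motif)) 0L else nchar(cfg$motif)

    sense <- random_rna(E, L)
    planted <- rep(FALSE, E)
    if (!is.null(cfg$motif) && cfg$plant_rate > 0) {
      anchor <- if (cfg$plant_site == "SS3") ss3_pos else ss5_pos
      a <- cfg$plant_window[1]
      bnd <- cfg$plant_window[2]
      if (anchor + a < 1 || anchor + bnd - 1 > L || bnd - a < k) {
        stop("planting window outside generated sequence", call. = FALSE)
      }
      planted <- runif(E) < cfg$plant_rate
      starts <- anchor + a +
        floor(runif(E) * (bnd - a - k + 1))  # uniform valid start
      for (e in which(planted)) {
        substr(sense[e], starts[e], starts[e] + k - 1L) <- cfg$motif
      }
    }

    # realized motif evidence in the planting window (0 for null runs)
    if (is.null(cfg$motif)) {
      N <- rep(0, E)
    } else {
      anchor <- if (cfg$plant_site == "SS3") ss3_pos else ss5_pos
      wseq <- substr(sense, anchor + cfg$plant_window[1],
                     anchor + cfg$plant_window[2] - 1L)
      km <- kmer_motif(cfg$motif)
      N <- vapply(wseq, count_motif, 0.0, motif = km, USE.NAMES = FALSE)
    }

    b_s <- rep(cfg$b, length.out = S)
    c_e <- rnorm(E, 0, cfg$baseline_sd)
    A <- if (is.null(cfg$motif)) rep(0, S) else
      unname(cfg$activity[cfg$conditions])
    Nc <- N - mean(N)
    Xlin <- matrix(b_s, E, S, byrow = TRUE) + c_e + outer(Nc, A)
    theta <- 1 / (1 + exp(-Xlin))
    incl <- matrix(rbinom(E * S, cfg$depth, as.vector(theta)), E, S)

    strand <- rep(c("+", "-"), length.out = E)
    chroms <- sprintf("gene%05d", seq_len(E))
    genomic <- ifelse(strand == "+", sense,
                      vapply(sense, rna_revcomp, "", USE.NAMES = FALSE))
    genome <- Biostrings::DNAStringSet(chartr("U", "T", genomic))
    names(genome) <- chroms

    # sense coordinates of the three exons, then genomic per strand
    sense_exons <- rbind(c(1L, Fl),
                         c(Fl + I + 1L, Fl + I + X),
                         c(Fl + 2L * I + X + 1L, L))
    ann <- list()
    jrows <- list()
    samples <- sprintf("%s_%d", cfg$conditions,
                       ave(seq_len(S), cfg$conditions, FUN = seq_along))
    for (e in seq_len(E)) {
      ex <- sense_exons
      if (strand[e] == "-") {
        ex <- cbind(L - ex[, 2] + 1L, L - ex[, 1] + 1L)[3:1, , drop = FALSE]
      }
      # ex rows are now in genomic order: flank, cassette, flank
      ann[[e]] <- data.frame(
        chrom = chroms[e],
        start = c(ex[, 1], ex[c(1, 3), 1]),
        end = c(ex[, 2], ex[c(1, 3), 2]),
        strand = strand[e],
        transcript_id = c(rep(paste0(chroms[e], ".incl"), 3),
                          rep(paste0(chroms[e], ".skip"), 2)),
        gene_id = chroms[e], stringsAsFactors = FALSE)
      j_up <- junction_id(chroms[e], ex[1, 2] + 1L, ex[2, 1] - 1L,
                          strand[e])
      j_dn <- junction_id(chroms[e], ex[2, 2] + 1L, ex[3, 1] - 1L,
                          strand[e])
      j_sk <- junction_id(chroms[e], ex[1, 2] + 1L, ex[3, 1] - 1L,
                          strand[e])
      counts <- rbind(incl[e, ], incl[e, ], cfg$depth - incl[e, ])
      jrows[[e]] <- data.frame(junction_id = c(j_up, j_dn, j_sk),
                               counts, stringsAsFactors = FALSE)
    }
    anndf <- do.call(rbind, ann)
    annotation <- GenomicRanges::GRanges(
      seqnames = anndf$chrom,
      ranges = IRanges::IRanges(anndf$start, anndf$end),
      strand = anndf$strand, type = "exon",
      transcript_id = anndf$transcript_id, gene_id = anndf$gene_id)
    junction_counts <- do.call(rbind, jrows)
    colnames(junction_counts) <- c("junction_id", samples)

    events <- select_cassette_exons(annotation, junction_counts,
                                    min_support = 10,
                                    min_exon_length = min(50, X))
    # truth keyed by event_id for alignment with the events object
    exon_g <- t(vapply(seq_len(E), function(e) {
      ex <- as.numeric(sense_exons[2, ])
      if (strand[e] == "-") ex <- c(L - ex[2] + 1, L - ex[1] + 1)
      ex
    }, c(0, 0)))
    event_id <- sprintf("%s:%d-%d:%s", chroms, as.integer(exon_g[, 1]),
                        as.integer(exon_g[, 2]), strand)
    truth <- list(
      A = setNames(A, samples), b = setNames(b_s, samples),
      N = setNames(N, event_id), c_e = setNames(c_e, event_id),
      planted = setNames(planted, event_id),
      theta = `dimnames<-`(theta, list(event_id, samples)),
      motif = cfg$motif, plant_site = cfg$plant_site,
      plant_window = cfg$plant_window, conditions = cfg$conditions)
    list(genome = genome, annotation = annotation,
         junction_counts = junction_counts, events = events,
         truth = truth, config = cfg)
  })
}

#' Simulate a tandem poly(A)-site dataset with planted activities
#'
#' Generates terminal exons with 2-3 tandem poly(A) sites on their own
#' chromosomes (alternating strands), plants the motif near sites, builds
#' `log2` usage as `y = Ntilde A*_s + c_p + c_{s,e} + Normal(0, sd)`,
#' converts to relative usage and draws per-site read counts from a
#' multinomial per exon and sample.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome`, `site_counts` (data.frame consumable by
#'   [build_pas_usage()]), `pas` (`"pas_events"`), and `truth`
#'   (`A`, per-site `N`, `y`, planting flags).
#' @export
simulate_pas_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 2L), {
    S <- cfg$n_samples
    nsites <- sample(cfg$sites_per_exon, cfg$n_pas_exons, replace = TRUE)
    P <- sum(nsites)
    exon_id <- rep(sprintf("texon%04d", seq_len(cfg$n_pas_exons)), nsites)
    site_idx <- sequence(nsites)
    site_id <- sprintf("%s.pas%d", exon_id, site_idx)
    k <- if (is.null(cfg$motif)) 0L else nchar(cfg$motif)
    a <- cfg$plant_window[1]
    bnd <- cfg$plant_window[2]

    chrom_of <- exon_id
    strand_exon <- rep(c("+", "-"), length.out = cfg$n_pas_exons)
    strand <- strand_exon[match(exon_id, unique(exon_id))]
    Lc <- 2 * cfg$pas_margin + max(nsites) * cfg$pas_spacing
    sense_pos <- cfg$pas_margin + site_idx * cfg$pas_spacing
    sense <- random_rna(cfg$n_pas_exons, Lc)

    planted <- rep(FALSE, P)
    if (!is.null(cfg$motif) && cfg$plant_rate > 0) {
      planted <- runif(P) < cfg$plant_rate
      starts <- sense_pos + a + floor(runif(P) * (bnd - a - k + 1))
      for (p in which(planted)) {
        ei <- match(exon_id[p], unique(exon_id))
        substr(sense[ei], starts[p], starts[p] + k - 1L) <- cfg$motif
      }
    }
    if (is.null(cfg$motif)) {
      N <- rep(0, P)
    } else {
      km <- kmer_motif(cfg$motif)
      N <- vapply(seq_len(P), function(p) {
        ei <- match(exon_id[p], unique(exon_id))
        count_motif(substr(sense[ei], sense_pos[p] + a,
                           sense_pos[p] + bnd - 1L), km)
      }, 0.0)
    }

    A <- if (is.null(cfg$motif)) rep(0, S) else
      unname(cfg$activity[cfg$conditions])
    exon_f <- factor(exon_id, levels = unique(exon_id))
    Nc <- N - ave(N, exon_f)
    c_p <- rnorm(P, 0, 1)
    c_se <- matrix(rnorm(cfg$n_pas_exons * S, 0, 0.5),
                   cfg$n_pas_exons, S)
    y <- outer(Nc, A) + c_p + c_se[as.integer(exon_f), ] +
      matrix(rnorm(P * S, 0, cfg$noise_sd), P, S)

    # per-exon, per-sample normalization to relative usage, then counts
    counts <- matrix(0L, P, S)
    for (ei in seq_len(cfg$n_pas_exons)) {
      idx <- which(as.integer(exon_f) == ei)
      for (s in seq_len(S)) {
        u <- 2^y[idx, s]
        u <- u / sum(u)
        counts[idx, s] <- rmultinom(1, cfg$pas_depth, u)[, 1]
      }
    }

    genomic <- ifelse(strand_exon == "+", sense,
                      vapply(sense, rna_revcomp, "", USE.NAMES = FALSE))
    genome <- Biostrings::DNAStringSet(chartr("U", "T", genomic))
    names(genome) <- unique(exon_id)
    position <- ifelse(strand == "+", sense_pos, Lc - sense_pos + 1L)

    samples <- sprintf("%s_%d", cfg$conditions,
                       ave(seq_len(S), cfg$conditions, FUN = seq_along))
    site_counts <- data.frame(site_id = site_id, exon_id = exon_id,
                              chrom = chrom_of, strand = strand,
                              position = position, counts,
                              stringsAsFactors = FALSE)
    colnames(site_counts)[-(1:5)] <- samples
    pas <- build_pas_usage(site_counts, pseudocount = 1)
    truth <- list(A = setNames(A, samples), N = setNames(N, site_id),
                  y = `dimnames<-`(y, list(site_id, samples)),
                  planted = setNames(planted, site_id),
                  motif = cfg$motif, plant_window = cfg$plant_window)
    list(genome = genome, site_counts = site_counts, pas = pas,
         truth = truth, config = cfg)
  })
}

#' Simulate foreground/background coverage tracks
#'
#' Background coverage is i.i.d. Poisson per position; the foreground is
#' Poisson with the rate multiplied by `fold` within the enrichment window
#' (sense offsets) of target sites only.
#'
#' @param genome_lengths named vector of chromosome lengths.
#' @param sites data.frame with `site_id`, `chrom`, `strand`, `position`.
#' @param targets character vector of target `site_id`s receiving
#'   enrichment.
#' @param enrich_window half-open sense-offset window `c(start, end)`.
#' @param fold enrichment factor (1 = no enrichment).
#' @param rate background Poisson rate per position.
#' @param seed RNG seed.
#' @return list with `fg` and `bg` [coverage_track()] objects.
#' @export
simulate_coverage <- function(genome_lengths, sites, targets,
                              enrich_window = c(-50, 0), fold = 3,
                              rate = 5, seed = 1) {
  with_seed(derive_seed(seed, 3L), {
    lam_fg <- lapply(genome_lengths, function(L) rep(rate, L))
    names(lam_fg) <- names(genome_lengths)
    for (i in which(sites$site_id %in% targets)) {
      chrom <- sites$chrom[i]
      offs <- seq(enrich_window[1], enrich_window[2] - 1L)
      pos <- if (sites$strand[i] == "+") sites$position[i] + offs else
        sites$position[i] - offs
      pos <- pos[pos >= 1 & pos <= genome_lengths[[chrom]]]
      lam_fg[[chrom]][pos] <- lam_fg[[chrom]][pos] * fold
    }
    fg_cov <- lapply(lam_fg, function(l) S4Vectors::Rle(rpois(length(l), l)))
    bg_cov <- lapply(genome_lengths, function(L)
      S4Vectors::Rle(rpois(L, rate)))
    names(bg_cov) <- names(genome_lengths)
    list(fg = coverage_track(as_rle_list(fg_cov)),
         bg = coverage_track(as_rle_list(bg_cov)))
  })
}

#' Write a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param file output path.
#' @export
write_bedgraph <- function(track, file) {
  gr <- GenomicRanges::bindAsGRanges(score = track$coverage)
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}
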