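#' Construct a position weight matrix record
#'
#' A PWM gives, for each position of a putative RNA-binding protein binding
#' site, the probability of observing each of the four bases. Matrices are
#' stored with one row per position and columns A, C, G, U (RNA alphabet;
#' motifs act on pre-mRNA, so DNA input is transcribed).
#'
#' @param pwm_id character motif identifier.
#' @param matrix numeric L x 4 matrix of base probabilities; columns in
#'   A, C, G, U order. Each row must sum to 1 within `1e-6`.
#' @param rbp_name name of the RBP the motif is assigned to.
#' @param gene_id gene identifier of the RBP.
#' @param species species annotation (e.g. `"Homo_sapiens"`).
#' @param mutated logical; `TRUE` for motifs derived from mutant proteins.
#' @param experiment free-text experiment description.
#' @return an object of class `"pwm"`.
#' @export
pwm <- function(pwm_id, matrix, rbp_name = NA_character_,
                gene_id = NA_character_, species = NA_character_,
                mutated = FALSE, experiment = NA_character_) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L || nrow(matrix) < 1L) {
    stop("PWM matrix must have L >= 1 rows and 4 columns (A,C,G,U)",
         call. = FALSE)
  }
  colnames(matrix) <- RNA_BASES
  if (any(matrix < -1e-12) || any(matrix > 1 + 1e-12)) {
    stop("PWM probabilities must lie in [0, 1]", call. = FALSE)
  }
  matrix[matrix < 0] <- 0
  if (any(abs(rowSums(matrix) - 1) > 1e-6)) {
    stop("PWM '", pwm_id, "': every position must sum to 1 within 1e-6",
         call. = FALSE)
  }
  structure(
    list(pwm_id = as.character(pwm_id), rbp_name = as.character(rbp_name),
         gene_id = as.character(gene_id), species = as.character(species),
         mutated = isTRUE(mutated), experiment = as.character(experiment),
         matrix = matrix),
    class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), %d nt, entropy %.2f bits\n",
              x$pwm_id, x$rbp_name, nrow(x$matrix), total_entropy(x)))
  invisible(x)
}

#' Total Shannon entropy of a PWM
#'
#' Sum over positions of `-sum_b p_b log2 p_b` (bits), with `0 log 0 = 0`.
#' Used to flag overly degenerate motifs: a fully uniform column contributes
#' 2 bits, a deterministic column 0 bits.
#'
#' @param pwm a [pwm()] object.
#' @return total entropy in bits.
#' @export
total_entropy <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  m <- pwm$matrix
  if (any(abs(rowSums(m) - 1) > 1e-6)) {
    stop("invalid PWM matrix: positions do not sum to 1", call. = FALSE)
  }
  ent <- ifelse(m > 0, -m * log2(m), 0)
  sum(ent)
}

# Per-position information content against a uniform background (bits).
position_ic <- function(pwm) {
  m <- pwm$matrix
  2 - rowSums(ifelse(m > 0, -m * log2(m), 0))
}

#' Core motif length of a PWM
#'
#' Length of the motif after trimming leading and trailing positions with
#' zero information content (IC below `1e-9` bits against a uniform
#' background). A fully uninformative PWM has core length 0.
#'
#' @param pwm a [pwm()] object.
#' @return integer core length.
#' @export
core_length <- function(pwm) {
  ic <- position_ic(pwm)
  informative <- which(ic >= 1e-9)
  if (length(informative) == 0L) return(0L)
  max(informative) - min(informative) + 1L
}

#' Construct a k-mer motif
#' @param sequence character k-mer over A, C, G, U (T accepted, transcribed).
#' @return an object of class `"kmer_motif"`.
#' @export
kmer_motif <- function(sequence) {
  sequence <- dna_to_rna(sequence)
  assert_rna(sequence)
  structure(list(sequence = sequence, k = nchar(sequence)),
            class = "kmer_motif")
}

#' Construct a homogeneous motif set
#'
#' @param members list of [pwm()] or [kmer_motif()] objects (not mixed).
#' @param provenance free-text description of where the set came from.
#' @return an object of class `"motif_set"` with elements `mode`
#'   (`"pwm"` or `"kmer"`), `members` (named list) and `provenance`.
#' @export
motif_set <- function(members, provenance = "") {
  if (length(members) == 0L) {
    return(structure(list(mode = "empty", members = list(),
                          provenance = provenance), class = "motif_set"))
  }
  is_pwm <- vapply(members, inherits, TRUE, what = "pwm")
  is_kmer <- vapply(members, inherits, TRUE, what = "kmer_motif")
  if (all(is_pwm)) {
    mode <- "pwm"
    ids <- vapply(members, `[[`, "", "pwm_id")
  } else if (all(is_kmer)) {
    mode <- "kmer"
    ids <- vapply(members, `[[`, "", "sequence")
  } else {
    stop("motif_set members must be all PWMs or all k-mers", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("motif ids must be unique within a motif_set", call. = FALSE)
  }
  names(members) <- ids
  structure(list(mode = mode, members = members, provenance = provenance),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> mode=%s, %d motifs (%s)\n",
              x$mode, length(x$members), x$provenance))
  invisible(x)
}

#' @export
length.motif_set <- function(x) length(x$members)

#' Motif identifiers of a motif set
#' @param x a [motif_set()].
#' @return character vector of motif ids.
#' @export
motif_ids <- function(x) {
  stopifnot(inherits(x, "motif_set"))
  names(x$members)
}

#' Enumerate all k-mers in a length range
#'
#' All `4^k` RNA k-mers for every k in `[kmin, kmax]`, in deterministic
#' lexicographic order (A < C < G < U) within each length, shortest first.
#'
#' @param kmin,kmax integer k-mer length bounds, `1 <= kmin <= kmax`.
#' @return a [motif_set()] in k-mer mode.
#' @export
enumerate_kmers <- function(kmin = 3L, kmax = 5L) {
  if (kmin < 1L || kmin > kmax) {
    stop("require 1 <= kmin <= kmax", call. = FALSE)
  }
  seqs <- unlist(lapply(kmin:kmax, function(k) {
    grid <- do.call(expand.grid,
                    c(rev(replicate(k, RNA_BASES, simplify = FALSE)),
                      stringsAsFactors = FALSE))
    # expand.grid varies the first factor fastest; reversed columns give
    # lexicographic order when pasted right-to-left
    apply(grid[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
  }))
  motif_set(lapply(seqs, kmer_motif), provenance = sprintf(
    "all k-mers, k in [%d, %d]", kmin, kmax))
}

#' Curate a list of PWM records
#'
#' Applies, in order, the six-stage filter used to build the analysis motif
#' catalog from a raw ATtRACT-style dump:
#' \enumerate{
#'   \item keep species `Homo_sapiens` (underscore/space insensitive);
#'   \item keep non-mutated records;
#'   \item collapse records sharing gene id + pwm id + experiment
#'     description, where any description containing "SELEX" counts as one
#'     description;
#'   \item cluster records with entrywise-identical matrices (probabilities
#'     rounded to 6 decimals): drop the whole cluster when it spans several
#'     RBPs (the matrix cannot be assigned unambiguously), keep a single
#'     record when it belongs to one RBP;
#'   \item keep core length ([core_length()]) between 4 and 7;
#'   \item keep total entropy ([total_entropy()]) at most `max_entropy`.
#' }
#'
#' @param records list of [pwm()] objects.
#' @param core_range integer length-2 vector, allowed core length range.
#' @param max_entropy maximum total entropy in bits.
#' @return list with `curated` (a [motif_set()]) and `audit` (data.frame of
#'   per-stage record counts, monotone non-increasing).
#' @export
curate_pwms <- function(records, core_range = c(4L, 7L), max_entropy = 10) {
  stopifnot(all(vapply(records, inherits, TRUE, what = "pwm")))
  audit <- data.frame(stage = c("input", "species", "not_mutated",
                                "dedup_experiment", "unambiguous_matrix",
                                "core_length", "entropy"),
                      n = NA_integer_)
  audit$n[1] <- length(records)

  norm_sp <- function(s) tolower(gsub("[ _]+", "_", s))
  records <- Filter(function(r) norm_sp(r$species) == "homo_sapiens", records)
  audit$n[2] <- length(records)

  records <- Filter(function(r) !isTRUE(r$mutated), records)
  audit$n[3] <- length(records)

  exp_key <- vapply(records, function(r) {
    e <- r$experiment
    if (grepl("SELEX", e, ignore.case = FALSE)) e <- "SELEX"
    paste(r$gene_id, r$pwm_id, e, sep = "\r")
  }, "")
  records <- records[!duplicated(exp_key)]
  audit$n[4] <- length(records)

  mat_key <- vapply(records, function(r) {
    paste(sprintf("%.6f", round(r$matrix, 6)), collapse = ",")
  }, "")
  keep <- logical(length(records))
  for (key in unique(mat_key)) {
    idx <- which(mat_key == key)
    rbps <- unique(vapply(records[idx], `[[`, "", "rbp_name"))
    if (length(rbps) == 1L) keep[idx[1]] <- TRUE
  }
  records <- records[keep]
  audit$n[5] <- length(records)

  cl <- vapply(records, core_length, 1L)
  records <- records[cl >= core_range[1] & cl <= core_range[2]]
  audit$n[6] <- length(records)

  ent <- vapply(records, total_entropy, 1.0)
  records <- records[ent <= max_entropy]
  audit$n[7] <- length(records)

  list(curated = motif_set(records, provenance = "curated PWM catalog"),
       audit = audit)
}

#' Read ATtRACT-style motif metadata and matrices
#'
#' The metadata file is a TSV with at least the columns `Matrix_id`,
#' `Gene_name`, `Gene_id`, `Organism`, `Mutated`, `Experiment_description`.
#' The matrix file holds blocks headed by `">matrix_id"` followed by one
#' whitespace-separated row of 4 probabilities (A, C, G, U) per motif
#' position. Rows that fail to parse are skipped with a warning, dropping
#' the affected record.
#'
#' @param db_file path to the metadata TSV.
#' @param matrix_file path to the PWM matrix text file.
#' @return list of [pwm()] objects, one per metadata row with a parseable
#'   matrix.
#' @export
read_attract_motifs <- function(db_file, matrix_file) {
  meta <- read.table(db_file, header = TRUE, sep = "\t",
                     quote = "", comment.char = "", stringsAsFactors = FALSE)
  needed <- c("Matrix_id", "Gene_name", "Gene_id", "Organism", "Mutated",
              "Experiment_description")
  missing <- setdiff(needed, colnames(meta))
  if (length(missing)) {
    stop("metadata file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  matrices <- read_pwm_matrices(matrix_file)
  records <- vector("list", nrow(meta))
  ok <- logical(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    mid <- as.character(meta$Matrix_id[i])
    m <- matrices[[mid]]
    if (is.null(m)) {
      warning("no parseable matrix for record '", mid, "'; skipped",
              call. = FALSE)
      next
    }
    rec <- tryCatch(
      pwm(pwm_id = mid, matrix = m, rbp_name = meta$Gene_name[i],
          gene_id = meta$Gene_id[i], species = meta$Organism[i],
          mutated = tolower(meta$Mutated[i]) %in% c("yes", "true", "1"),
          experiment = meta$Experiment_description[i]),
      error = function(e) {
        warning("record '", mid, "': ", conditionMessage(e), "; skipped",
                call. = FALSE)
        NULL
      })
    if (!is.null(rec)) {
      records[[i]] <- rec
      ok[i] <- TRUE
    }
  }
  records[ok]
}

# Parse ">id" blocks of whitespace-separated probability rows.
read_pwm_matrices <- function(matrix_file) {
  lines <- readLines(matrix_file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    stop("no '>' headers found in matrix file", call. = FALSE)
  }
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (j in seq_along(headers)) {
    id <- sub("^>\\s*", "", lines[headers[j]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[seq(headers[j] + 1L, bounds[j + 1L] - 1L)]
    rows <- lapply(body, function(l) {
      vals <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
      if (length(vals) != 4L || anyNA(vals)) NULL else vals
    })
    if (any(vapply(rows, is.null, TRUE)) || length(rows) == 0L) {
      warning("unparseable matrix block '", id, "'", call. = FALSE)
      next
    }
    out[[id]] <- do.call(rbind, rows)
  }
  out
}

#' Write a curated motif set
#'
#' Writes a summary TSV (`pwm_id`, `rbp`, `core_length`, `entropy`) and a
#' matrix file in the same `">id"`-block dialect read by
#' [read_attract_motifs()].
#'
#' @param set a [motif_set()] in PWM mode.
#' @param summary_file,matrix_file output paths.
#' @return invisibly, the summary data.frame.
#' @export
write_motif_set <- function(set, summary_file, matrix_file) {
  stopifnot(inherits(set, "motif_set"), set$mode == "pwm")
  summary <- data.frame(
    pwm_id = motif_ids(set),
    rbp = vapply(set$members, `[[`, "", "rbp_name"),
    core_length = vapply(set$members, core_length, 1L),
    entropy = vapply(set$members, total_entropy, 1.0),
    row.names = NULL)
  write.table(summary, summary_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  con <- file(matrix_file, "w")
  on.exit(close(con))
  for (m in set$members) {
    writeLines(paste0(">", m$pwm_id), con)
    apply(m$matrix, 1, function(r) {
      writeLines(paste(sprintf("%.6f", r), collapse = "\t"), con)
    })
  }
  invisible(summary)
}
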