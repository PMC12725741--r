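#' Per-monomer protein-binding affinity profiles
#'
#' An `affinity_profile` describes the protein-binding energy landscape of a
#' coarse-grained DNA chain in which each monomer stands for 10 bp. Four DNA
#' models are supported: a homogeneous chain where every monomer binds
#' proteins with 2.0 kBT; two block-heterogeneous chains (`het1`, `het2`)
#' built from high- and low-affinity blocks; and a sequence-mapped chain
#' whose affinities derive from the AT content of consecutive 10-bp windows.
#'
#' @param affinities numeric vector of per-monomer binding energies (kBT).
#' @param kind_labels integer class per monomer (e.g. AT count 0-10, or a
#'   block id for the block models).
#' @param model_name one of `"homogeneous"`, `"het1"`, `"het2"`,
#'   `"sequence_mapped"`.
#' @return An object of class `affinity_profile` with fields `n_monomers`,
#'   `affinities`, `kind_labels`, `model_name`.
#' @export
affinity_profile <- function(affinities, kind_labels, model_name) {
  affinities <- as.numeric(affinities)
  kind_labels <- as.integer(kind_labels)
  if (length(affinities) == 0L)
    stop("affinity profile must contain at least one monomer")
  if (length(kind_labels) != length(affinities))
    stop("kind_labels and affinities must have equal length")
  if (any(!is.finite(affinities)) ||
      any(affinities < 0.1 - 1e-9) || any(affinities > 4.0 + 1e-9))
    stop("affinities must lie in [0.1, 4.0] kBT")
  structure(
    list(
      n_monomers = length(affinities),
      affinities = affinities,
      kind_labels = kind_labels,
      model_name = match.arg(model_name,
                             c("homogeneous", "het1", "het2",
                               "sequence_mapped"))
    ),
    class = "affinity_profile"
  )
}

#' @export
print.affinity_profile <- function(x, ...) {
  cat(sprintf("Affinity profile '%s': %d monomers (%d bp)\n",
              x$model_name, x$n_monomers, 10L * x$n_monomers))
  cat(sprintf("  affinity range %.2f-%.2f kBT, mean %.3f kBT, %d kinds\n",
              min(x$affinities), max(x$affinities), mean(x$affinities),
              length(unique(x$kind_labels))))
  invisible(x)
}

#' Block-copolymer affinity profiles for the three designed DNA models
#'
#' Builds the designed binding landscapes:
#' \describe{
#'   \item{homogeneous}{every monomer 2.0 kBT.}
#'   \item{het1}{an ABA block copolymer: the central 50\% of monomers bind at
#'     2.25 kBT, flanked by 25\% on each side at 1.75 kBT, so the chain mean
#'     stays exactly 2.0 kBT.}
#'   \item{het2}{two high-affinity blocks (2.25 kBT, 20\% of the chain each)
#'     separated and flanked by low-affinity blocks (0.1 kBT), laid out
#'     symmetrically as L-H-L-H-L with five equal blocks.}
#' }
#' Block sizes scale proportionally with `n_monomers`, so shortened chains
#' keep the same layout; `n_monomers` must be divisible by 4 (`het1`) or 5
#' (`het2`).
#'
#' @param model_name `"homogeneous"`, `"het1"` or `"het2"`.
#' @param n_monomers chain length in monomers (default 500, i.e. 5 kb).
#' @return An [affinity_profile]. `kind_labels` are 0 for low- and 1 for
#'   high-affinity monomers (all 1 for the homogeneous model).
#' @examples
#' p <- build_block_profile("het1", 500)
#' mean(p$affinities)  # exactly 2.0
#' @export
build_block_profile <- function(model_name, n_monomers = 500L) {
  model_name <- match.arg(model_name, c("homogeneous", "het1", "het2"))
  n_monomers <- as.integer(n_monomers)
  if (is.na(n_monomers) || n_monomers < 1L)
    stop("n_monomers must be a positive integer")
  if (model_name == "homogeneous") {
    return(affinity_profile(rep(2.0, n_monomers), rep(1L, n_monomers),
                            "homogeneous"))
  }
  if (model_name == "het1") {
    if (n_monomers %% 4L != 0L)
      stop("het1 layout (25%/50%/25%) needs n_monomers divisible by 4, got ",
           n_monomers)
    q <- n_monomers %/% 4L
    aff <- c(rep(1.75, q), rep(2.25, 2L * q), rep(1.75, q))
    kind <- c(rep(0L, q), rep(1L, 2L * q), rep(0L, q))
    return(affinity_profile(aff, kind, "het1"))
  }
  # het2: symmetric five-block L-H-L-H-L layout
  if (n_monomers %% 5L != 0L)
    stop("het2 layout (five equal blocks) needs n_monomers divisible by 5, ",
         "got ", n_monomers)
  b <- n_monomers %/% 5L
  aff <- c(rep(0.1, b), rep(2.25, b), rep(0.1, b), rep(2.25, b), rep(0.1, b))
  kind <- c(rep(0L, b), rep(1L, b), rep(0L, b), rep(1L, b), rep(0L, b))
  affinity_profile(aff, kind, "het2")
}

#' Map the AT count of a 10-bp window to a binding energy
#'
#' Eleven monomer kinds are distinguished by the number of A/T bases in the
#' 10-bp window a monomer represents. The map is linear between the two
#' endpoints of the modeled affinity range: 0 AT bases gives 0.1 kBT, 10 AT
#' bases gives 4.0 kBT, i.e. `0.1 + at_count * 0.39` kBT.
#'
#' @param at_count integer (vectorized) number of A/T bases, 0-10.
#' @return binding energy in kBT.
#' @export
at_count_to_affinity <- function(at_count) {
  at_count <- as.integer(at_count)
  if (any(is.na(at_count)) || any(at_count < 0L) || any(at_count > 10L))
    stop("at_count must be an integer in 0..10")
  0.1 + at_count * (4.0 - 0.1) / 10
}

#' Convert a DNA sequence to an affinity profile
#'
#' Partitions the sequence into consecutive non-overlapping 10-bp windows
#' from the 5' end (one monomer each; a trailing partial window is dropped)
#' and assigns each monomer the affinity of its AT count via
#' [at_count_to_affinity()]. `N` and other ambiguity codes count as non-AT.
#'
#' @param dna_sequence a single character string (case-insensitive) over
#'   A/C/G/T/N, or a `Biostrings::DNAString`-coercible object.
#' @return An [affinity_profile] with `kind_labels` = AT count per monomer.
#' @examples
#' sequence_to_profile(strrep("AT", 10))$affinities  # two monomers at 4 kBT
#' @export
sequence_to_profile <- function(dna_sequence) {
  seq <- toupper(as.character(dna_sequence))
  if (length(seq) != 1L || is.na(seq) || nchar(seq) < 10L)
    stop("dna_sequence must be a single string of length >= 10")
  if (!grepl("^[ACGTN]+$", seq))
    stop("dna_sequence may only contain A, C, G, T, N")
  n_win <- nchar(seq) %/% 10L
  if (n_win < 1L) stop("sequence shorter than one 10-bp window")
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]][seq_len(10L * n_win)]
  is_at <- bases == "A" | bases == "T"
  if (!any(bases %in% c("A", "C", "G", "T")))
    stop("sequence contains no unambiguous bases")
  at_counts <- as.integer(colSums(matrix(is_at, nrow = 10L)))
  affinity_profile(at_count_to_affinity(at_counts), at_counts,
                   "sequence_mapped")
}

#' Read a FASTA record into an affinity profile
#'
#' @param path FASTA file (possibly multi-record).
#' @param id optional record id; defaults to the first record.
#' @return An [affinity_profile].
#' @export
fasta_to_profile <- function(path, id = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to read FASTA files")
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  if (!is.null(id)) {
    hit <- which(sub("\\s.*$", "", names(set)) == id)
    if (length(hit) == 0L) stop("record '", id, "' not found in ", path)
    set <- set[hit[1L]]
  }
  sequence_to_profile(as.character(set[[1L]]))
}

#' Export an affinity profile as TSV
#'
#' Columns: `monomer_index` (0-based), `at_count` (kind label), and
#' `affinity_kBT`.
#'
#' @param profile an [affinity_profile].
#' @param path output file.
#' @return the written data frame, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "affinity_profile"))
  df <- data.frame(
    monomer_index = seq_len(profile$n_monomers) - 1L,
    at_count = profile$kind_labels,
    affinity_kBT = profile$affinities
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# --- concentration <-> particle count -------------------------------------

#' Avogadro constant (1/mol)
#' @keywords internal
.N_AVOGADRO <- 6.02214076e23

#' Convert a bulk protein concentration to a particle count
#'
#' The simulation box is measured in units of the bead diameter sigma
#' (3.4 nm by default: 10 bp at 0.34 nm/bp). A molar concentration rho_p
#' (micromolar) in that box corresponds to `round(rho_p * N_A * V)` proteins
#' with V the box volume in liters.
#'
#' @param rho_uM concentration in micromolar.
#' @param box numeric length-3 box dimensions in sigma.
#' @param sigma_nm bead diameter in nanometers (default 3.4).
#' @return integer protein count.
#' @examples
#' concentration_to_count(84.5, c(80, 80, 600))  # ~7680 proteins
#' @export
concentration_to_count <- function(rho_uM, box, sigma_nm = 3.4) {
  stopifnot(length(box) == 3L, all(box > 0), sigma_nm > 0)
  if (!is.finite(rho_uM) || rho_uM < 0) stop("rho_uM must be >= 0")
  v_liters <- prod(box) * (sigma_nm * 1e-9)^3 * 1e3  # m^3 -> L
  as.integer(round(rho_uM * 1e-6 * .N_AVOGADRO * v_liters))
}

#' Convert a particle count back to a concentration (micromolar)
#'
#' Exact inverse of [concentration_to_count()] up to the rounding of the
#' count.
#'
#' @param n_proteins integer count.
#' @inheritParams concentration_to_count
#' @return concentration in micromolar.
#' @export
count_to_concentration <- function(n_proteins, box, sigma_nm = 3.4) {
  stopifnot(length(box) == 3L, all(box > 0), sigma_nm > 0, n_proteins >= 0)
  v_liters <- prod(box) * (sigma_nm * 1e-9)^3 * 1e3
  n_proteins / (.N_AVOGADRO * v_liters) * 1e6
}
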