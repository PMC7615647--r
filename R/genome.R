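# Gap-construct arithmetic: locating Cas9-nickase sites on a genome and
# the nick-to-nick separation that defines the length of an engineered
# ssDNA gap.

#' Locate SpCas9 (D10A nickase) cut sites for a crRNA spacer
#'
#' Finds perfect protospacer matches (spacer followed by an NGG PAM) on
#' both strands and returns the cut coordinate of each: SpCas9 cuts
#' between protospacer positions 17 and 18, i.e. 3 bp 5' of the PAM. The
#' returned coordinate is the (1-based) position of the last base on the
#' 5' side of the cut, on the reference strand.
#'
#' @param genome A single DNA sequence: character string, or a
#'   `Biostrings::DNAString`/`DNAStringSet` of length 1, or the path to a
#'   single-record FASTA file.
#' @param spacer 20-nt spacer sequence (DNA alphabet; RNA `U` accepted).
#' @return Data frame: `start`, `end` (protospacer span on the reference
#'   strand), `strand`, `cut_after` (nick coordinate).
#' @export
locate_nick_sites <- function(genome, spacer) {
  seq <- as_genome_string(genome)
  spacer <- toupper(chartr("Uu", "TT", spacer))
  if (!grepl("^[ACGT]+$", spacer)) stop("spacer must be a DNA/RNA sequence")
  L <- nchar(spacer)
  hits <- list()
  for (m in fixed_matches(spacer, seq)) {         # protospacer on + strand
    s <- m; e <- m + L - 1L
    pam <- substr(seq, e + 1L, e + 3L)
    if (grepl("^[ACGT]GG$", pam))
      hits[[length(hits) + 1L]] <- data.frame(start = s, end = e,
                                              strand = "+",
                                              cut_after = e - 3L)
  }
  rc <- revcomp(spacer)
  for (m in fixed_matches(rc, seq)) {             # protospacer on - strand
    s <- m; e <- m + L - 1L
    pam <- substr(seq, s - 3L, s - 1L)
    if (s > 3L && grepl("^CC[ACGT]$", pam))
      hits[[length(hits) + 1L]] <- data.frame(start = s, end = e,
                                              strand = "-",
                                              cut_after = s + 2L)
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), cut_after = integer()))
  out <- do.call(rbind, hits)
  out[order(out$start), , drop = FALSE]
}

#' Nick-to-nick separation for a pair of crRNA spacers
#'
#' The separation in nucleotides between the two nicks produced by a
#' Cas9-D10A nickase programmed with two crRNAs; for a gapped-DNA
#' construct this is the length of the ssDNA gap released on melting.
#' Errors unless each spacer has exactly one protospacer match.
#'
#' @param genome See [locate_nick_sites()].
#' @param spacer1,spacer2 The two 20-nt spacers.
#' @return Separation in nt (positive integer).
#' @export
nick_site_separation <- function(genome, spacer1, spacer2) {
  seq <- as_genome_string(genome)
  h1 <- locate_nick_sites(seq, spacer1)
  h2 <- locate_nick_sites(seq, spacer2)
  if (nrow(h1) != 1L || nrow(h2) != 1L)
    stop(sprintf(
      "need exactly one protospacer match per spacer (got %d and %d)",
      nrow(h1), nrow(h2)))
  abs(h2$cut_after - h1$cut_after)
}

as_genome_string <- function(genome) {
  if (is.character(genome) && length(genome) == 1L &&
      !grepl("^[ACGTNacgtn]+$", genome) && file.exists(genome)) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      ss <- Biostrings::readDNAStringSet(genome)
      if (length(ss) != 1L) stop("FASTA must contain exactly one record")
      return(toupper(as.character(ss[[1]])))
    }
    lines <- readLines(genome)
    return(toupper(paste(lines[!startsWith(lines, ">")], collapse = "")))
  }
  if (inherits(genome, "DNAStringSet")) {
    if (length(genome) != 1L) stop("need exactly one sequence")
    genome <- genome[[1]]
  }
  if (inherits(genome, "DNAString")) return(toupper(as.character(genome)))
  if (!is.character(genome) || length(genome) != 1L)
    stop("genome must be a single sequence or FASTA path")
  toupper(genome)
}

fixed_matches <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

revcomp <- function(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
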