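#' Generate a completely random amino-acid sequence
#'
#' Draws each position i.i.d. uniformly over the 20 standard amino acids.
#' Integers 0--19 map to residues in alphabetical one-letter order
#' ([amino_acids]); the default length of 70 residues matches a short
#' single-domain protein.
#'
#' @param length Sequence length in residues (>= 1).
#' @param seed Integer seed for reproducibility (optional; when `NULL` the
#'   current RNG stream is used).
#' @param id Identifier for the record.
#' @return List of class `sequence_record`: `id`, `sequence`, `length`.
#' @export
generate_random_sequence <- function(length = 70, seed = NULL, id = "rnd_1") {
  if (!is.numeric(length) || length < 1)
    stop("length must be >= 1", call. = FALSE)
  length <- as.integer(length)
  draw <- function() paste(sample(amino_acids, length, replace = TRUE),
                           collapse = "")
  seq <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(id = id, sequence = seq, length = length),
            class = "sequence_record")
}

#' Generate a library of random sequences through a novelty filter
#'
#' Repeatedly draws uniform random sequences and keeps those accepted by
#' `filter` until `n` records are collected. The filter abstracts the
#' database-similarity screen of the original design (sequences similar to
#' known proteins are rejected); the default accepts everything.
#'
#' @param n Number of accepted sequences required (>= 1).
#' @param length Sequence length in residues.
#' @param filter Predicate `function(sequence_string) -> TRUE/FALSE`.
#' @param max_attempts Attempt budget before giving up.
#' @param seed Integer seed.
#' @return List of `n` [sequence_record][generate_random_sequence] objects,
#'   with attribute `rejected` giving the number of discarded draws.
#' @export
generate_library <- function(n, length = 70, filter = function(s) TRUE,
                             max_attempts = 1000L * n, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.function(filter)) stop("filter must be a function", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    out <- vector("list", n)
    accepted <- 0L; attempts <- 0L
    while (accepted < n) {
      if (attempts >= max_attempts)
        stop(sprintf("filter accepted %d of %d sequences after %d attempts",
                     accepted, n, attempts), call. = FALSE)
      attempts <- attempts + 1L
      s <- paste(sample(amino_acids, length, replace = TRUE), collapse = "")
      if (isTRUE(filter(s))) {
        accepted <- accepted + 1L
        out[[accepted]] <- structure(
          list(id = sprintf("rnd_%05d", accepted), sequence = s,
               length = as.integer(length)),
          class = "sequence_record")
      }
    }
    attr(out, "rejected") <- attempts - n
    out
  })
}

#' k-mer overlap novelty filter
#'
#' Offline stand-in for a database-similarity screen: rejects a sequence
#' when it shares at least one k-mer with any of the reference sequences.
#'
#' @param reference Character vector of reference sequences, or a FASTA path.
#' @param k k-mer size.
#' @return Predicate suitable for [generate_library()].
#' @export
kmer_novelty_filter <- function(reference, k = 8) {
  if (length(reference) == 1L && file.exists(reference))
    reference <- vapply(seqinr::read.fasta(reference, seqtype = "AA",
                                           as.string = TRUE),
                        function(x) toupper(as.character(x)), character(1))
  kmers <- function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  }
  ref_kmers <- unique(unlist(lapply(toupper(reference), kmers)))
  function(s) !any(kmers(toupper(s)) %in% ref_kmers)
}

#' Write sequence records to FASTA
#'
#' @param records List of [sequence_record][generate_random_sequence] objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path) {
  seqinr::write.fasta(lapply(records, function(r) r$sequence),
                      names = vapply(records, function(r) r$id, character(1)),
                      file.out = path, as.string = TRUE)
  invisible(path)
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf(">%s (%d aa)\n%s\n", x$id, x$length, x$sequence))
  invisible(x)
}
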