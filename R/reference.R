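#' The canonical 18-bp I-SceI recognition sequence (top strand)
#' @export
ISCEI_RECOGNITION <- "TAGGGATAACAGGGTAAT"

#' The SacI restriction motif restored by HR gene conversion
#' @export
SACI_MOTIF <- "GAGCTC"

#' DR-white reporter construct geometry
#'
#' Holds the wild-type *white* amplicon and the Sce.*white* amplicon, which
#' differs by an insertion carrying the 18-bp I-SceI recognition sequence.
#' HR gene conversion deletes the full insertion (23 bp by default) and
#' restores the SacI motif `GAGCTC`, so the HR-diagnostic shift in an indel
#' spectrum is `-insertion_len`.  Coordinates are 1-based, closed, top
#' strand only (the assay is strand-fixed by the sequencing primer).
#'
#' @param wildtype_seq wild-type amplicon sequence (character, ACGT).
#' @param sce_seq the same amplicon carrying the break-site insertion.
#' @param recognition_start 1-based start of the recognition sequence within
#'   `sce_seq`.
#' @param insertion_len insertion size in bp; its removal restores the
#'   wild type (default 23).
#' @param cut_offset bp from `recognition_start` to the modelled break point
#'   (default 9, inside the recognition site).
#' @param recognition_seq the endonuclease recognition sequence
#'   (default [ISCEI_RECOGNITION]).
#' @param sacI_motif restriction motif restored at the locus on HR
#'   (default [SACI_MOTIF]).
#' @return A validated `reference_construct` list with the above fields plus
#'   `insertion_start`, the 1-based start of the insertion within `sce_seq`.
#' @details Validation enforces: `nchar(sce_seq) - nchar(wildtype_seq) ==
#'   insertion_len`; removing the `insertion_len` bases spanning the
#'   insertion from `sce_seq` reproduces `wildtype_seq` byte for byte; the
#'   recognition sequence occurs at `recognition_start`; and `wildtype_seq`
#'   carries `sacI_motif` across the insertion locus.
#' @seealso [locate_recognition_site()], [expected_hr_shift()],
#'   [make_reference()] for a synthetic construct generator.
#' @export
reference_construct <- function(wildtype_seq, sce_seq, recognition_start,
                                insertion_len = 23L, cut_offset = 9L,
                                recognition_seq = ISCEI_RECOGNITION,
                                sacI_motif = SACI_MOTIF) {
  wildtype_seq <- toupper(as.character(wildtype_seq))
  sce_seq <- toupper(as.character(sce_seq))
  recognition_start <- as.integer(recognition_start)
  insertion_len <- as.integer(insertion_len)
  if (nchar(sce_seq) - nchar(wildtype_seq) != insertion_len)
    stop("length(sce_seq) - length(wildtype_seq) must equal insertion_len",
         call. = FALSE)
  if (substr(sce_seq, recognition_start,
             recognition_start + nchar(recognition_seq) - 1L) !=
      recognition_seq)
    stop("recognition sequence not found at recognition_start", call. = FALSE)
  ins_start <- find_insertion_start(wildtype_seq, sce_seq, insertion_len)
  if (is.na(ins_start))
    stop("removing insertion_len bases from sce_seq never restores ",
         "wildtype_seq", call. = FALSE)
  if (insertion_len > 0L) {
    lo <- max(1L, ins_start - nchar(sacI_motif))
    hi <- min(nchar(wildtype_seq), ins_start + nchar(sacI_motif) - 1L)
    if (!grepl(sacI_motif, substr(wildtype_seq, lo, hi), fixed = TRUE))
      stop("wildtype_seq does not carry ", sacI_motif,
           " at the insertion locus", call. = FALSE)
  }
  structure(list(wildtype_seq = wildtype_seq, sce_seq = sce_seq,
                 recognition_seq = recognition_seq,
                 recognition_start = recognition_start,
                 insertion_start = ins_start,
                 insertion_len = insertion_len,
                 cut_offset = as.integer(cut_offset),
                 sacI_motif = sacI_motif),
            class = "reference_construct")
}

# first insertion start i such that dropping sce[i .. i+len-1] gives wildtype;
# NA when no such i exists
find_insertion_start <- function(wt, sce, len) {
  if (len == 0L) return(if (identical(wt, sce)) 1L else NA_integer_)
  n <- nchar(wt)
  m <- nchar(sce)
  wt_c <- strsplit(wt, "", fixed = TRUE)[[1]]
  sc_c <- strsplit(sce, "", fixed = TRUE)[[1]]
  mism <- which(wt_c != sc_c[seq_len(n)])
  i <- if (length(mism)) mism[1] else n + 1L
  if (i + len - 1L > m) return(NA_integer_)
  cand <- paste0(substr(sce, 1L, i - 1L), substr(sce, i + len, m))
  if (identical(cand, wt)) i else NA_integer_
}

#' @export
print.reference_construct <- function(x, ...) {
  cat("DR-white reference construct\n",
      "  wildtype amplicon: ", nchar(x$wildtype_seq), " bp\n",
      "  Sce amplicon:      ", nchar(x$sce_seq), " bp (+",
      x$insertion_len, " bp insertion at ", x$insertion_start, ")\n",
      "  recognition site:  ", x$recognition_seq, " at ",
      x$recognition_start, ", cut offset ", x$cut_offset, "\n", sep = "")
  invisible(x)
}

#' Locate the modelled break point in the Sce amplicon
#'
#' Requires the recognition sequence to occur exactly once in `sce_seq` and
#' returns `recognition_start + cut_offset` (1-based position in `sce_seq`).
#'
#' @param ref a [reference_construct].
#' @return integer break position.
#' @export
locate_recognition_site <- function(ref) {
  stopifnot(inherits(ref, "reference_construct"))
  hits <- gregexpr(ref$recognition_seq, ref$sce_seq, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (length(hits) == 0L)
    stop("recognition sequence absent from sce_seq", call. = FALSE)
  if (length(hits) > 1L)
    stop("recognition sequence occurs ", length(hits),
         " times in sce_seq; break site ambiguous", call. = FALSE)
  as.integer(hits[1] + ref$cut_offset)
}

#' HR-diagnostic indel shift for a construct
#'
#' HR gene conversion removes the whole break-site insertion, so the
#' signature in the indel spectrum is a deletion of `insertion_len` bases:
#' `-23` for the canonical construct.
#'
#' @param ref a [reference_construct].
#' @return signed integer shift (deletions negative).
#' @export
expected_hr_shift <- function(ref) {
  stopifnot(inherits(ref, "reference_construct"))
  -ref$insertion_len
}

#' Read / write a reference construct as FASTA
#'
#' The FASTA holds two records named `wildtype` and `sce_white`; the
#' construct metadata (`recognition_start`, `cut_offset`, `insertion_len`)
#' travels separately as function arguments, mirroring the plain-text config
#' of the file interface.
#'
#' @param path FASTA file path.
#' @param ... metadata passed on to [reference_construct()]
#'   (`recognition_start`, `insertion_len`, `cut_offset`, ...).
#' @return `read_reference_fasta()` returns a [reference_construct];
#'   `write_reference_fasta()` returns `path` invisibly.
#' @export
read_reference_fasta <- function(path, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!all(c("wildtype", "sce_white") %in% names(seqs)))
    stop("FASTA must contain records named 'wildtype' and 'sce_white'",
         call. = FALSE)
  reference_construct(as.character(seqs[["wildtype"]]),
                      as.character(seqs[["sce_white"]]), ...)
}

#' @param ref a [reference_construct].
#' @rdname read_reference_fasta
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "reference_construct"))
  seqs <- Biostrings::DNAStringSet(c(wildtype = ref$wildtype_seq,
                                     sce_white = ref$sce_seq))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
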