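#' GQ construct table, loop descriptors and motif detection
#'
#' The constructs studied here are partial-duplex DNAs: an 18 nt stem
#' (annealed to a labelled complement) followed by a single-stranded
#' G-rich overhang obeying the quadruplex motif G3+ N1-7 G3+ N1-7 G3+
#' N1-7 G3+.  Constructs are named by their three loop lengths ("233" =
#' loops of 2, 3, 3 nt) or by their repeated loop sequence ("TTA").
#'
#' @name constructs
NULL

# 18 nt duplex stem shared by every construct in the packaged table
gq_stem <- function() "TGGCGACGGCAGCGAGGC"

# loop sequences for constructs named by a repeated three-letter loop
loop_name_table <- function() {
  list(TTT = c("TTT", "TTT", "TTT"),
       TTA = c("TTA", "TTA", "TTA"),
       TAA = c("TAA", "TAA", "TAA"),
       AAA = c("AAA", "AAA", "AAA"))
}

#' Load the packaged GQ construct table
#'
#' Reads the packaged TSV of DNA constructs, strips whitespace and
#' dye/biotin annotations (e.g. `/3'Cy3/`, `/iamino/`, `/3'Bio/`) out of the
#' sequences into a metadata column, expands the `(T)25` shorthand, and
#' annotates each construct with its stem/overhang split, GQ-forming flag,
#' loop sequences and loop lengths.
#'
#' @param path path to the construct TSV (columns `name`, `sequence`,
#'   `notes`). Defaults to the fixture shipped with the package.
#' @return a data frame of class `gq_construct_table` with columns
#'   `name`, `sequence` (clean, uppercase, annotations removed),
#'   `sequence_raw` (as printed in the fixture), `labels` (stripped
#'   annotations, comma separated), `stem`, `overhang`, `gq_forming`,
#'   `loop1`, `loop2`, `loop3` (loop sequences, empty for non-GQ rows),
#'   `loop_len1..3`, `total_loop_length` and `notes`.
#' @export
#' @examples
#' tab <- load_construct_table()
#' tab[tab$name == "133", c("loop1", "loop2", "loop3", "total_loop_length")]
load_construct_table <- function(path = system.file("extdata", "constructs.tsv",
                                                    package = "gqfret")) {
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    stopf("construct table fixture not found: '%s'", path %||% "<NULL>")
  }
  tab <- tryCatch(
    utils::read.delim(path, colClasses = "character", quote = "",
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) stopf("construct table '%s' is corrupt: %s", path,
                              conditionMessage(e)))
  need <- c("name", "sequence", "notes")
  if (!all(need %in% names(tab))) {
    stopf("construct table '%s' is missing columns: %s", path,
          paste(setdiff(need, names(tab)), collapse = ", "))
  }

  raw <- tab$sequence
  labels <- vapply(raw, function(s) {
    ann <- regmatches(s, gregexpr("/[^/]*/", s))[[1]]
    paste(gsub("/", "", ann, fixed = TRUE), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  seq_clean <- gsub("/[^/]*/", "", raw)
  seq_clean <- gsub("\\s+", "", seq_clean)
  # expand the (T)25-style homopolymer shorthand
  seq_clean <- vapply(seq_clean, function(s) {
    m <- regexec("\\(([ACGT])\\)([0-9]+)", s)[[1]]
    if (m[1] == -1) return(s)
    groups <- regmatches(s, regexec("\\(([ACGT])\\)([0-9]+)", s))[[1]]
    sub("\\([ACGT]\\)[0-9]+",
        strrep(groups[2], as.integer(groups[3])), s)
  }, character(1), USE.NAMES = FALSE)
  seq_clean <- toupper(seq_clean)
  bad <- grepl("[^ACGT]", seq_clean)
  if (any(bad)) {
    stopf("construct table '%s': non-ACGT characters in sequence of %s",
          path, paste(tab$name[bad], collapse = ", "))
  }

  stem <- gq_stem()
  has_stem <- startsWith(seq_clean, stem)
  overhang <- ifelse(has_stem, substring(seq_clean, nchar(stem) + 1L), NA_character_)

  loops <- lapply(seq_len(nrow(tab)), function(i) {
    construct_loops(tab$name[i], overhang[i])
  })
  loop_seq <- do.call(rbind, lapply(loops, function(l) l$sequences))
  out <- data.frame(
    name = tab$name,
    sequence = seq_clean,
    sequence_raw = raw,
    labels = labels,
    stem = ifelse(has_stem, stem, NA_character_),
    overhang = overhang,
    gq_forming = vapply(loops, function(l) l$gq_forming, logical(1)),
    loop1 = loop_seq[, 1], loop2 = loop_seq[, 2], loop3 = loop_seq[, 3],
    loop_len1 = nchar(loop_seq[, 1]),
    loop_len2 = nchar(loop_seq[, 2]),
    loop_len3 = nchar(loop_seq[, 3]),
    notes = tab$notes,
    stringsAsFactors = FALSE
  )
  out$total_loop_length <- out$loop_len1 + out$loop_len2 + out$loop_len3
  class(out) <- c("gq_construct_table", "data.frame")
  out
}

# derive loop sequences for one construct; digit names are authoritative,
# letter names use the packaged mapping, cMyc is hard-mapped (its GA loop
# abuts a G-run, so greedy run maximisation would mis-register it)
construct_loops <- function(name, overhang) {
  empty <- list(gq_forming = FALSE, sequences = c("", "", ""))
  if (is.na(overhang)) return(empty)
  if (name == "cMyc") {
    return(list(gq_forming = TRUE, sequences = c("T", "GA", "T")))
  }
  if (grepl("^[0-9]{3}$", name)) {
    lens <- as.integer(strsplit(name, "")[[1]])
    hits <- detect_gq_motif(overhang, max_loop = max(lens, 7L))
    if (nrow(hits) == 1L) {
      seqs <- vapply(1:3, function(j) {
        substr(overhang, hits[[paste0("loop", j, "_start")]] + 1L,
               hits[[paste0("loop", j, "_start")]] + hits[[paste0("loop", j, "_len")]])
      }, character(1))
      return(list(gq_forming = TRUE, sequences = seqs))
    }
    return(empty)
  }
  lt <- loop_name_table()
  if (name %in% names(lt)) {
    return(list(gq_forming = TRUE, sequences = lt[[name]]))
  }
  empty
}

#' Re-serialise a construct table to its fixture format
#'
#' Writes `name`, `sequence_raw` and `notes` back to TSV; loading the
#' packaged fixture and re-serialising it reproduces the file byte for byte.
#'
#' @param tab a `gq_construct_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_construct_table <- function(tab, path) {
  stopifnot(inherits(tab, "gq_construct_table"))
  out <- data.frame(name = tab$name, sequence = tab$sequence_raw,
                    notes = tab$notes, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Look up one construct from the packaged table
#'
#' @param name construct label, e.g. `"233"`, `"TTA"`, `"cMyc"`.
#' @param tab optionally a pre-loaded table.
#' @return a one-row `gq_construct_table`.
#' @export
lookup_construct <- function(name, tab = load_construct_table()) {
  i <- match(name, tab$name)
  if (is.na(i)) stopf("unknown construct '%s'", name)
  tab[i, , drop = FALSE]
}

#' Detect the G-quadruplex motif in a DNA sequence
#'
#' Scans the sense strand for four runs of at least `min_run` guanines
#' separated by three loops of 1 to `max_loop` nucleotides.  G-runs are
#' maximised greedily; when overlapping registrations exist the leftmost
#' one is reported and scanning resumes after the hit (hits do not
#' overlap).  Coordinates are 0-based half-open.
#'
#' @param sequence DNA string over A/C/G/T (case-insensitive).
#' @param min_run minimum G-run length (>= 2), default 3.
#' @param max_loop maximum loop length (>= 1), default 7. Constructs with
#'   9 nt loops (e.g. "199") require raising this.
#' @return data frame with one row per hit: `start`, `end` (0-based
#'   half-open), `loop1_len..loop3_len`, `loop1_start..loop3_start`
#'   (0-based).
#' @export
#' @examples
#' detect_gq_motif("GGGTGGGTGGGTGGG")
detect_gq_motif <- function(sequence, min_run = 3L, max_loop = 7L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (min_run < 2L) stopf("min_run must be >= 2")
  if (max_loop < 1L) stopf("max_loop must be >= 1")
  s <- toupper(sequence)
  if (grepl("[^ACGT]", s)) stopf("sequence contains non-ACGT characters")

  empty <- data.frame(start = integer(0), end = integer(0),
                      loop1_len = integer(0), loop2_len = integer(0),
                      loop3_len = integer(0), loop1_start = integer(0),
                      loop2_start = integer(0), loop3_start = integer(0))
  m <- gregexpr(sprintf("G{%d,}", min_run), s)[[1]]
  if (m[1] == -1) return(empty)
  run_start <- as.integer(m)                      # 1-based
  run_len <- attr(m, "match.length")
  n_runs <- length(run_start)
  if (n_runs < 4L) return(empty)

  hits <- list()
  i <- 1L
  while (i + 3L <= n_runs) {
    gaps <- run_start[(i + 1L):(i + 3L)] -
      (run_start[i:(i + 2L)] + run_len[i:(i + 2L)])
    if (all(gaps >= 1L & gaps <= max_loop)) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = run_start[i] - 1L,
        end = run_start[i + 3L] + run_len[i + 3L] - 1L,
        loop1_len = gaps[1], loop2_len = gaps[2], loop3_len = gaps[3],
        loop1_start = run_start[i] + run_len[i] - 1L,
        loop2_start = run_start[i + 1L] + run_len[i + 1L] - 1L,
        loop3_start = run_start[i + 2L] + run_len[i + 2L] - 1L)
      i <- i + 4L
    } else {
      i <- i + 1L
    }
  }
  if (!length(hits)) return(empty)
  do.call(rbind, hits)
}

#' Parse a loop descriptor into loop lengths and sequences
#'
#' Three-digit names map directly to integer loop lengths (thymine loops);
#' three-letter names map through the packaged loop-sequence table.
#'
#' @param name descriptor such as `"233"`, `"919"` or `"TAA"`.
#' @return list with `loop_lengths` (integer triple), `loop_sequences`
#'   (character triple) and `total_loop_length`.
#' @export
#' @examples
#' parse_loop_descriptor("533")
parse_loop_descriptor <- function(name) {
  stopifnot(length(name) == 1L, is.character(name))
  if (grepl("^[0-9]{3}$", name)) {
    lens <- as.integer(strsplit(name, "")[[1]])
    if (any(lens == 0L)) stopf("loop lengths must be positive in '%s'", name)
    return(list(loop_lengths = lens,
                loop_sequences = strrep("T", lens),
                total_loop_length = sum(lens)))
  }
  lt <- loop_name_table()
  if (name %in% names(lt)) {
    seqs <- lt[[name]]
    return(list(loop_lengths = nchar(seqs), loop_sequences = seqs,
                total_loop_length = sum(nchar(seqs))))
  }
  stopf("unknown loop descriptor '%s'", name)
}
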