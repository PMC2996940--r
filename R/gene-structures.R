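#' Parse gene models from an annotation flat file
#'
#' Reads CDS features from an EMBL- or GenBank-dialect flat file and
#' returns one gene model per CDS. Intron positions are implied by the
#' `join(...)` / `join(complement(...))` exon coordinates. Reverse-strand
#' joins are normalized to coding order (first coding exon first).
#' Entries with fuzzy coordinates (`<` or `>`) and CDS features without a
#' `protein_id` are skipped with a warning; unparseable location strings
#' are likewise reported per record and skipped.
#'
#' The gene identifier is taken from the `gene` qualifier (EMBL) or the
#' `db_xref="GeneID:..."` qualifier (GenBank); the spliceform identifier
#' is the `protein_id`. The organelle is read from the record's `source`
#' feature (`/organelle` qualifier), defaulting to `"nuclear"`.
#'
#' @param text Flat-file content as a single string or character vector of
#'   lines.
#' @param dialect `"embl"` or `"genbank"`.
#' @param species Optional species label overriding the file's
#'   `OS`/`ORGANISM` line.
#' @return A tibble with columns `species`, `gene_id`, `spliceform_id`,
#'   `organelle`, `strand`, `segments` (list column of tibbles with
#'   1-based inclusive `start`, `end` in coding order) and `translation`.
#' @examples
#' txt <- paste(
#'   "ID   X; SV 1; linear; DNA; STD; HUM; 200 BP.",
#'   "OS   Homo sapiens",
#'   "FT   CDS             join(1..30,101..160)",
#'   "FT                   /gene=\"G1\"",
#'   "FT                   /protein_id=\"P1\"",
#'   "FT                   /translation=\"MAAAAAAAAAWLLLLLLLLLV\"",
#'   "//", sep = "\n")
#' parse_gene_records(txt, "embl")
#' @export
parse_gene_records <- function(text, dialect = c("embl", "genbank"),
                               species = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  recs <- split_records(lines)
  out <- purrr::map(recs, parse_one_record, dialect = dialect,
                    species_override = species)
  dplyr::bind_rows(out)
}

split_records <- function(lines) {
  ends <- which(startsWith(lines, "//"))
  if (length(ends) == 0L) return(list(lines))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  purrr::map2(starts, ends, ~ lines[.x:.y])
}

parse_one_record <- function(lines, dialect, species_override = NULL) {
  species <- species_override %||% extract_species(lines, dialect)
  feats <- collect_features(lines, dialect)
  organelle <- "nuclear"
  src <- purrr::detect(feats, ~ .x$key == "source")
  if (!is.null(src) && !is.null(src$qualifiers$organelle)) {
    organelle <- normalize_organelle(src$qualifiers$organelle)
  }
  cds <- purrr::keep(feats, ~ .x$key == "CDS")
  rows <- purrr::map(cds, function(ft) {
    q <- ft$qualifiers
    spliceform_id <- q$protein_id
    if (is.null(spliceform_id)) {
      warn_ipcon("CDS at '%s' has no protein_id; skipped",
                 substr(ft$location, 1, 40))
      return(NULL)
    }
    gene_id <- if (dialect == "embl") q$gene else genbank_gene_id(q)
    if (is.null(gene_id)) gene_id <- spliceform_id
    if (grepl("[<>]", ft$location)) {
      warn_ipcon("CDS %s has fuzzy coordinates; skipped", spliceform_id)
      return(NULL)
    }
    loc <- tryCatch(parse_location(ft$location), error = function(e) e)
    if (inherits(loc, "error")) {
      warn_ipcon("CDS %s: unparseable location '%s'; skipped",
                 spliceform_id, ft$location)
      return(NULL)
    }
    if (is.null(q$translation)) {
      warn_ipcon("CDS %s has no translation; skipped", spliceform_id)
      return(NULL)
    }
    tibble::tibble(
      species = species %||% NA_character_,
      gene_id = gene_id,
      spliceform_id = spliceform_id,
      organelle = organelle,
      strand = loc$strand,
      segments = list(loc$segments),
      translation = gsub("[^A-Za-z*]", "", q$translation)
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}

extract_species <- function(lines, dialect) {
  pat <- if (dialect == "embl") "^OS   +(.+?)\\s*$" else "^ +ORGANISM +(.+?)\\s*$"
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  sub(pat, "\\1", hit[[1]])
}

genbank_gene_id <- function(q) {
  dbx <- q$db_xref
  if (is.null(dbx)) return(NULL)
  gid <- grep("^GeneID:", dbx, value = TRUE)
  if (length(gid) == 0L) return(NULL)
  sub("^GeneID:", "", gid[[1]])
}

normalize_organelle <- function(x) {
  x <- tolower(x)
  if (grepl("mitochond", x)) return("mitochondrial")
  if (grepl("plastid|chloroplast", x)) return("plastid")
  "nuclear"
}

# Collect features as list(key, location, qualifiers) from one record.
# EMBL feature lines carry the "FT" prefix; GenBank indents with spaces.
collect_features <- function(lines, dialect) {
  if (dialect == "embl") {
    fl <- grep("^FT ", lines, value = TRUE)
    body <- substring(fl, 6)
  } else {
    fstart <- grep("^FEATURES", lines)
    if (length(fstart) == 0L) return(list())
    cand <- lines[(fstart[1] + 1L):length(lines)]
    stop_at <- grep("^(ORIGIN|CONTIG|//)", cand)
    if (length(stop_at) > 0L) cand <- cand[seq_len(stop_at[1] - 1L)]
    fl <- grep("^ {5}", cand, value = TRUE)
    body <- substring(fl, 6)
  }
  if (length(body) == 0L) return(list())
  is_new <- !startsWith(body, " ")
  idx <- cumsum(is_new)
  feats <- split(body, idx)
  purrr::map(unname(feats), function(chunk) {
    key <- sub("\\s.*$", "", chunk[[1]])
    rest <- c(sub("^\\S+\\s+", "", chunk[[1]]), trimws(chunk[-1]))
    qstart <- which(startsWith(rest, "/"))
    loc_lines <- if (length(qstart)) rest[seq_len(min(qstart) - 1L)] else rest
    qual_lines <- if (length(qstart)) rest[min(qstart):length(rest)] else character()
    list(key = key,
         location = paste(loc_lines, collapse = ""),
         qualifiers = parse_qualifiers(qual_lines))
  })
}

# Qualifier lines -> named list; repeated qualifiers (db_xref) accumulate.
# Quoted values may continue over several lines (translation).
parse_qualifiers <- function(lines) {
  quals <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    m <- regmatches(ln, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", ln))[[1]]
    if (length(m) == 0L) { i <- i + 1L; next }
    name <- m[[2]]
    val <- m[[4]]
    if (startsWith(val, "\"")) {
      val <- substring(val, 2)
      while (!grepl("\"\\s*$", val) && i < length(lines)) {
        i <- i + 1L
        nxt <- lines[[i]]
        sep <- if (name == "translation") "" else " "
        val <- paste(val, nxt, sep = sep)
      }
      val <- sub("\"\\s*$", "", val)
    }
    quals[[name]] <- c(quals[[name]], val)
    i <- i + 1L
  }
  quals
}

# Parse a CDS location string into coding-ordered segments + strand.
parse_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "forward"
  if (grepl("^complement\\(", loc)) {
    strand <- "reverse"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- split_toplevel_commas(loc)
  seg <- purrr::map(parts, function(p) {
    if (grepl("^complement\\(", p)) {
      strand <<- "reverse"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^[0-9]+$", p)) {
      s <- as.integer(p); e <- s
    } else {
      m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1]]
      if (length(m) == 0L) abort_ipcon("bad location element '%s'", p)
      s <- as.integer(m[[2]]); e <- as.integer(m[[3]])
    }
    if (s > e) abort_ipcon("segment start > end in '%s'", p)
    tibble::tibble(start = s, end = e)
  })
  segments <- dplyr::bind_rows(seg)
  segments <- if (strand == "forward") {
    dplyr::arrange(segments, .data$start)
  } else {
    dplyr::arrange(segments, dplyr::desc(.data$start))
  }
  check_nonoverlapping(segments)
  list(segments = segments, strand = strand)
}

split_toplevel_commas <- function(x) {
  chars <- strsplit(x, "")[[1]]
  depth <- 0L
  cuts <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  purrr::map2_chr(starts, ends, ~ paste(chars[.x:.y], collapse = ""))
}

check_nonoverlapping <- function(segments) {
  if (nrow(segments) < 2L) return(invisible(TRUE))
  g <- dplyr::arrange(segments, .data$start)
  if (any(g$start[-1] <= g$end[-nrow(g)])) {
    abort_ipcon("overlapping exon segments")
  }
  invisible(TRUE)
}

#' Coding-nucleotide offsets of the introns implied by exon segments
#'
#' Each junction between consecutive exon segments (in coding order) is an
#' intron. Offset `k` means the intron lies between coding nucleotide
#' `k - 1` and `k` (0-based), i.e. `k` coding nucleotides precede it.
#'
#' @param segments Tibble with `start`, `end` (1-based inclusive) in
#'   coding order, or an integer vector of segment lengths.
#' @return Integer vector of offsets, one per junction (empty for a
#'   single-exon gene).
#' @examples
#' intron_offsets(c(30L, 60L))
#' @export
intron_offsets <- function(segments) {
  lens <- if (is.data.frame(segments)) {
    check_nonoverlapping(segments)
    abs(segments$end - segments$start) + 1L
  } else {
    as.integer(segments)
  }
  if (length(lens) < 2L) return(integer())
  utils::head(cumsum(lens), -1L)
}

#' Map intron positions onto protein coordinates
#'
#' Converts each coding-nucleotide intron offset `k` into a protein mark:
#' `residue_index = floor(k / 3)` (0-based), `phase = k mod 3`. Phase 0
#' introns precede the codon; phase 1/2 introns interrupt it. Either way
#' the residue encoded by that codon carries the mark, which is the
#' codon-level conservation criterion used throughout (an intron may
#' "slide" up to 2 nt and still hit the same codon). Marks landing at or
#' beyond the protein length (i.e. in the stop codon) are dropped with a
#' warning. Two introns marking the same residue with different phases are
#' both kept.
#'
#' @param models Gene-model tibble from [parse_gene_records()].
#' @return Protein-record tibble: `species`, `gene_id`, `spliceform_id`,
#'   `organelle`, `sequence` (upper case), `length`, and `marks` (list
#'   column of tibbles with `residue_index`, `phase`).
#' @export
mark_proteins <- function(models) {
  rows <- purrr::pmap(models, function(species, gene_id, spliceform_id,
                                       organelle, strand, segments,
                                       translation, ...) {
    seq <- toupper(sub("\\*$", "", translation))
    p <- nchar(seq)
    total <- sum(abs(segments$end - segments$start) + 1L)
    if (total != 3L * p && total != 3L * (p + 1L)) {
      abort_ipcon(
        "record %s: coding length %d incompatible with protein length %d",
        spliceform_id, total, p)
    }
    offs <- intron_offsets(segments)
    marks <- tibble::tibble(residue_index = offs %/% 3L, phase = offs %% 3L)
    beyond <- marks$residue_index >= p
    if (any(beyond)) {
      warn_ipcon("record %s: %d intron mark(s) inside/after the stop codon dropped",
                 spliceform_id, sum(beyond))
      marks <- marks[!beyond, , drop = FALSE]
    }
    marks <- dplyr::arrange(marks, .data$residue_index, .data$phase)
    tibble::tibble(species = species, gene_id = gene_id,
                   spliceform_id = spliceform_id, organelle = organelle,
                   sequence = seq, length = p, marks = list(marks))
  })
  dplyr::bind_rows(rows)
}

#' Select the longest spliceform per gene
#'
#' Removes exact duplicates within a gene (identical sequence and
#' identical marks; the lexicographically smallest spliceform id is kept),
#' then flags the longest remaining spliceform of each `(species,
#' gene_id)` as primary, breaking length ties by lexicographic spliceform
#' id. Shorter spliceforms are retained (with `primary = FALSE`) so they
#' can be re-added to extended clusters before scoring.
#'
#' @param records Protein-record tibble (see [mark_proteins()]).
#' @return The records tibble, duplicates removed, with a logical
#'   `primary` column.
#' @export
select_spliceforms <- function(records) {
  sig <- purrr::map_chr(records$marks, function(m) {
    paste(m$residue_index, m$phase, sep = ":", collapse = ",")
  })
  records <- records %>%
    dplyr::mutate(.sig = paste(.data$sequence, sig, sep = "#")) %>%
    dplyr::arrange(.data$species, .data$gene_id, .data$spliceform_id) %>%
    dplyr::distinct(.data$species, .data$gene_id, .data$.sig,
                    .keep_all = TRUE) %>%
    dplyr::select(-".sig")
  records %>%
    dplyr::group_by(.data$species, .data$gene_id) %>%
    dplyr::mutate(primary = dplyr::row_number(
      order(-.data$length, .data$spliceform_id)) == 1L) %>%
    dplyr::ungroup()
}

#' Read and write marked FASTA
#'
#' Marked FASTA is protein FASTA in which a lower-case residue encodes an
#' intron mark on that residue's codon. Headers are
#' `species|gene_id|spliceform_id` with an optional fourth `organelle`
#' field. Intron phase is not representable in this format and is read
#' back as `NA`.
#'
#' @param path For reading: a file path or the text itself (anything
#'   containing a newline or starting with `>` is treated as text). For
#'   writing: the output file path.
#' @return `read_marked_fasta()` returns a protein-record tibble;
#'   `write_marked_fasta()` invisibly returns `path`.
#' @examples
#' read_marked_fasta(">hsa|g1|t1\nMKlS\n")
#' @export
read_marked_fasta <- function(path) {
  lines <- if (length(path) == 1L && !grepl("[\n>]", path)) {
    readLines(path)
  } else {
    unlist(strsplit(paste(path, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines)]
  hdr_at <- which(startsWith(lines, ">"))
  if (length(hdr_at) == 0L) abort_ipcon("no FASTA headers found")
  ends <- c(hdr_at[-1] - 1L, length(lines))
  rows <- purrr::map2(hdr_at, ends, function(h, e) {
    fields <- strsplit(substring(lines[[h]], 2), "|", fixed = TRUE)[[1]]
    if (!(length(fields) %in% c(3L, 4L))) {
      abort_ipcon("line %d: malformed marked-FASTA header '%s'",
                  h, lines[[h]])
    }
    seq_raw <- paste(lines[(h + 1L):e], collapse = "")
    seq_raw <- gsub("\\s", "", seq_raw)
    chars <- strsplit(seq_raw, "")[[1]]
    low <- which(chars %in% letters) - 1L
    marks <- tibble::tibble(residue_index = as.integer(low),
                            phase = rep(NA_integer_, length(low)))
    tibble::tibble(
      species = fields[[1]], gene_id = fields[[2]],
      spliceform_id = fields[[3]],
      organelle = if (length(fields) == 4L) fields[[4]] else "nuclear",
      sequence = toupper(seq_raw), length = nchar(seq_raw),
      marks = list(marks))
  })
  dplyr::bind_rows(rows)
}

#' @param records Protein-record tibble to write.
#' @param width Line-wrap width for sequences.
#' @rdname read_marked_fasta
#' @export
write_marked_fasta <- function(records, path, width = 60L) {
  out <- purrr::pmap(records, function(species, gene_id, spliceform_id,
                                       organelle, sequence, marks, ...) {
    hdr <- sprintf(">%s|%s|%s|%s", species, gene_id, spliceform_id, organelle)
    chars <- strsplit(sequence, "")[[1]]
    mi <- marked_residues(marks) + 1L
    chars[mi] <- tolower(chars[mi])
    seq <- paste(chars, collapse = "")
    c(hdr, substring(seq, seq(1L, nchar(seq), width),
                     pmin(seq(1L, nchar(seq), width) + width - 1L, nchar(seq))))
  })
  writeLines(unlist(out), path)
  invisible(path)
}
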