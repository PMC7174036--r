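# Readers and writers for every external format the toolkit touches.
# All TSVs are UTF-8, tab-separated; lines starting with "#" are comments;
# the first non-comment line is the header.

#' Read a tab-separated table with "#" comment lines
#'
#' @param path file path
#' @param header logical, first non-comment line is a header
#' @return data.frame with character columns (no factor conversion)
#' @keywords internal
read_tsv_raw <- function(path, header = TRUE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path,
    header = header, sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = "character", blank.lines.skip = TRUE
  )
}

write_tsv_raw <- function(df, path, comments = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
}

#' Read contigs from a FASTA file
#'
#' The header token up to the first whitespace becomes the contig id; contig
#' length is computed from the sequence.
#'
#' @param path path to a FASTA file
#' @return a data.frame with columns `contig_id`, `length_bp`, `sequence`
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">C1 desc", "ACGT"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("no sequences in FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate contig id(s) in ", path, ": ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  data.frame(
    contig_id = ids,
    length_bp = Biostrings::width(seqs),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
}

#' Write contigs to a FASTA file
#'
#' @param contigs data.frame with columns `contig_id` and `sequence`
#' @param path output path
#' @param line_width sequence wrap width (default 60)
#' @return invisibly, the path
#' @export
write_fasta <- function(contigs, path, line_width = 60L) {
  if (nrow(contigs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (!"sequence" %in% names(contigs) || anyNA(contigs$sequence) ||
    any(!nzchar(contigs$sequence))) {
    stop("all records must carry a sequence to be written as FASTA",
      call. = FALSE
    )
  }
  seqs <- Biostrings::DNAStringSet(contigs$sequence)
  names(seqs) <- contigs$contig_id
  Biostrings::writeXStringSet(seqs, path, width = as.integer(line_width))
  invisible(path)
}

#' Taxonomic ranks used throughout the toolkit
#'
#' Six ranks, phylum through species, with their single-letter identifiers.
#'
#' @return named character vector: names are rank names, values rank letters
#' @export
taxonomy_ranks <- function() {
  c(
    phylum = "P", class = "C", order = "O",
    family = "F", genus = "G", species = "S"
  )
}

#' Read a per-contig taxonomic lineage table
#'
#' Supports Kaiju-style outputs via a column dialect. Lineages are split on
#' ";" with surrounding whitespace stripped; lineages shorter than six ranks
#' are padded at the tail with "NA"; unclassified contigs (status "U") map to
#' an all-"NA" lineage.
#'
#' @param path TSV path
#' @param dialect one of `"kaiju3col+lineage"` (columns: status C/U, contig
#'   id, taxon id, lineage), `"plain"` (contig id, lineage)
#' @param drop_domain if TRUE and a lineage has seven fields, the leading
#'   field is treated as a domain/superkingdom and dropped
#' @return named list: contig id -> character vector of 6 rank strings
#'   (phylum..species, "NA" allowed)
#' @export
read_lineage_table <- function(path, dialect = c("kaiju3col+lineage", "plain"),
                               drop_domain = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  n_ranks <- length(taxonomy_ranks())
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (dialect == "kaiju3col+lineage") {
      if (length(fields) < 2L) {
        stop("unreadable lineage row at line ", line_no[i], call. = FALSE)
      }
      status <- trimws(fields[[1]])
      id <- trimws(fields[[2]])
      lin_str <- if (length(fields) >= 4L) fields[[4]] else ""
      if (!status %in% c("C", "U")) {
        stop("unreadable lineage row at line ", line_no[i],
          ": status must be C or U",
          call. = FALSE
        )
      }
      if (status == "U") lin_str <- ""
    } else {
      if (length(fields) < 1L || !nzchar(trimws(fields[[1]]))) {
        stop("unreadable lineage row at line ", line_no[i], call. = FALSE)
      }
      id <- trimws(fields[[1]])
      lin_str <- if (length(fields) >= 2L) fields[[2]] else ""
    }
    if (!nzchar(id)) {
      stop("unreadable lineage row at line ", line_no[i], call. = FALSE)
    }
    if (id %in% names(out)) {
      stop("contig listed twice in lineage table: ", id, call. = FALSE)
    }
    lin <- trimws(strsplit(lin_str, ";", fixed = TRUE)[[1]])
    lin <- lin[nzchar(lin)]
    if (drop_domain && length(lin) == n_ranks + 1L) {
      lin <- lin[-1L]
    }
    if (length(lin) > n_ranks) {
      stop("lineage with more than ", n_ranks, " ranks at line ", line_no[i],
        call. = FALSE
      )
    }
    if (length(lin) < n_ranks) {
      lin <- c(lin, rep("NA", n_ranks - length(lin)))
    }
    out[[id]] <- lin
  }
  out
}

#' Read per-sample metadata
#'
#' @param path TSV with columns `sample_id`, `role` (AL or PL), `depth_cm`,
#'   `total_mapped_reads`
#' @return data.frame with typed columns, one row per sample
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_raw(path)
  required <- c("sample_id", "role", "depth_cm", "total_mapped_reads")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- data.frame(
    sample_id = df$sample_id,
    role = df$role,
    depth_cm = as.numeric(df$depth_cm),
    total_mapped_reads = as.numeric(df$total_mapped_reads),
    stringsAsFactors = FALSE
  )
  validate_sample_table(out)
  out
}

validate_sample_table <- function(samples) {
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids in sample table", call. = FALSE)
  }
  if (!all(samples$role %in% c("AL", "PL"))) {
    stop("sample role must be AL or PL", call. = FALSE)
  }
  if (any(is.na(samples$depth_cm)) || any(samples$depth_cm < 0)) {
    stop("depth_cm must be non-negative", call. = FALSE)
  }
  if (any(is.na(samples$total_mapped_reads)) ||
    any(samples$total_mapped_reads <= 0)) {
    stop("total_mapped_reads must be positive", call. = FALSE)
  }
  invisible(samples)
}

write_sample_table <- function(samples, path) {
  write_tsv_raw(samples, path)
}

#' Read a contig-by-sample coverage table
#'
#' @param path TSV with a `contig_id` column and one numeric column per
#'   sample; blank cells are read as 0
#' @param samples optional sample metadata (see [read_sample_table()]); when
#'   given, every sample column must appear in the metadata
#' @param state whether the file holds raw or already-normalized coverage
#' @return a [coverage_matrix()] in the given state
#' @export
read_coverage_table <- function(path, samples = NULL,
                                state = c("raw", "normalized")) {
  state <- match.arg(state)
  df <- read_tsv_raw(path)
  if (!"contig_id" %in% names(df)) {
    stop("coverage table must have a contig_id column", call. = FALSE)
  }
  sample_ids <- setdiff(names(df), "contig_id")
  if (!length(sample_ids)) {
    stop("coverage table has no sample columns", call. = FALSE)
  }
  if (!is.null(samples)) {
    unknown <- setdiff(sample_ids, samples$sample_id)
    if (length(unknown)) {
      stop("coverage sample column(s) absent from metadata: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
  }
  vals <- vapply(sample_ids, function(s) {
    x <- df[[s]]
    x[!nzchar(trimws(x))] <- "0"
    as.numeric(x)
  }, numeric(nrow(df)))
  vals <- matrix(vals,
    nrow = nrow(df),
    dimnames = list(df$contig_id, sample_ids)
  )
  if (anyNA(vals)) stop("non-numeric coverage value", call. = FALSE)
  if (any(vals < 0)) stop("negative coverage value", call. = FALSE)
  coverage_matrix(vals, state = state)
}

#' Write a coverage matrix as TSV
#'
#' @param mat a [coverage_matrix()]
#' @param path output path
#' @param comments header comment lines (written with a leading "# ")
#' @return invisibly, the path
#' @export
write_coverage_table <- function(mat, path, comments = character()) {
  stopifnot(inherits(mat, "coverage_matrix"))
  df <- data.frame(
    contig_id = rownames(mat$values), mat$values,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv_raw(df, path, comments = comments)
  invisible(path)
}

#' Read gene-to-KO annotations (GhostKOALA-style two-column TSV)
#'
#' The contig id is derived from the gene id; the default pattern strips a
#' final `_<integer>` suffix (the Prodigal gene-numbering convention). Rows
#' with an empty KO field are retained with `ko_id = NA`.
#'
#' @param path two-column TSV: gene id, KO id (may be empty); no header
#' @param gene_id_pattern regex with one capture group extracting the contig
#'   id from a gene id
#' @param gene_contig_map optional data.frame (`gene_id`, `contig_id`)
#'   overriding pattern-based linkage
#' @return data.frame with columns `gene_id`, `contig_id`, `ko_id`
#' @export
read_ko_table <- function(path, gene_id_pattern = "^(.*)_[0-9]+$",
                          gene_contig_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  gene_id <- vapply(fields, function(f) trimws(f[[1]]), character(1))
  ko_id <- vapply(fields, function(f) {
    if (length(f) >= 2L) trimws(f[[2]]) else ""
  }, character(1))
  ko_id[!nzchar(ko_id)] <- NA_character_
  if (!is.null(gene_contig_map)) {
    idx <- match(gene_id, gene_contig_map$gene_id)
    if (anyNA(idx)) {
      stop("gene id(s) absent from gene->contig map: ",
        paste(gene_id[is.na(idx)], collapse = ", "),
        call. = FALSE
      )
    }
    contig_id <- gene_contig_map$contig_id[idx]
  } else {
    ok <- grepl(gene_id_pattern, gene_id)
    if (!all(ok)) {
      stop("gene id(s) not matching pattern '", gene_id_pattern, "': ",
        paste(gene_id[!ok], collapse = ", "),
        call. = FALSE
      )
    }
    contig_id <- sub(gene_id_pattern, "\\1", gene_id)
  }
  data.frame(
    gene_id = gene_id, contig_id = contig_id, ko_id = ko_id,
    stringsAsFactors = FALSE
  )
}

#' Read KEGG Module definitions
#'
#' Each row maps a module id to its member KO identifiers. A module is
#' treated as a plain set of KOs; duplicates within a module are collapsed
#' and module size is the count of distinct KOs.
#'
#' @param path TSV: module id, then comma- or whitespace-separated KO ids;
#'   no header
#' @return named list of character vectors (module id -> distinct KO ids)
#' @export
read_module_definitions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    mid <- trimws(fields[[1]])
    kos <- if (length(fields) >= 2L) {
      unlist(strsplit(fields[[2]], "[,[:space:]]+"))
    } else {
      character()
    }
    kos <- unique(trimws(kos))
    kos <- kos[nzchar(kos)]
    if (!length(kos)) {
      stop("module with zero KOs: ", mid, call. = FALSE)
    }
    if (mid %in% names(out)) {
      stop("module listed twice: ", mid, call. = FALSE)
    }
    out[[mid]] <- kos
  }
  out
}

write_module_definitions <- function(modules, path) {
  lines <- vapply(names(modules), function(m) {
    paste0(m, "\t", paste(modules[[m]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
}

write_lineage_table <- function(lineages, path) {
  lines <- vapply(names(lineages), function(id) {
    paste0("C\t", id, "\t0\t", paste(lineages[[id]], collapse = "; "))
  }, character(1))
  writeLines(lines, path)
}

write_ko_table <- function(annotations, path) {
  ko <- annotations$ko_id
  ko[is.na(ko)] <- ""
  writeLines(paste0(annotations$gene_id, "\t", ko), path)
}
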