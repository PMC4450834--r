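#' Read an is-a hierarchy from file
#'
#' Accepts either a two-column tab-separated edge list with header
#' `child_id<TAB>parent_id`, or a minimal OBO file (`[Term]` stanzas with
#' `id:`, `name:`, `synonym:` and `is_a:` lines; all other tags and stanza
#' types are ignored). The format is sniffed from the content unless forced.
#'
#' @param path Path to the hierarchy file.
#' @param synonym_path Optional path to a tab-separated synonym table
#'   `concept_id<TAB>synonym`, one row per synonym (merged with any synonyms
#'   found in an OBO file).
#' @param format `"auto"` (default), `"tsv"` or `"obo"`.
#' @return A validated [ontology()] object.
#' @export
read_ontology <- function(path, synonym_path = NULL,
                          format = c("auto", "tsv", "obo")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_ontosim(sprintf("Hierarchy file not found: %s", path), "io")
  }
  lines <- readr::read_lines(path)
  if (format == "auto") {
    format <- if (any(stringr::str_detect(lines, "^\\[Term\\]\\s*$")) ||
                  any(stringr::str_starts(lines, "format-version:")))
      "obo" else "tsv"
  }
  syn <- NULL
  if (!is.null(synonym_path)) {
    syn <- read_synonym_table(synonym_path)
  }
  if (format == "tsv") {
    parsed <- parse_edge_tsv(lines, path)
    ontology(parsed, synonyms = syn)
  } else {
    parsed <- parse_obo(lines, path)
    syn <- bind_rows(parsed$synonyms, syn)
    ontology(parsed$edges, synonyms = syn, names = parsed$names)
  }
}

read_synonym_table <- function(path) {
  if (!file.exists(path)) {
    abort_ontosim(sprintf("Synonym file not found: %s", path), "io")
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(concept_id = character(0), synonym = character(0)))
  }
  parts <- stringr::str_split_fixed(lines, "\t", 3)
  has_header <- identical(tolower(parts[1, 1]), "concept_id")
  if (has_header) parts <- parts[-1, , drop = FALSE]
  if (nrow(parts) == 0) {
    return(tibble(concept_id = character(0), synonym = character(0)))
  }
  bad <- which(parts[, 2] == "")
  if (length(bad) > 0) {
    abort_ontosim(
      sprintf("Synonym table line %d lacks a tab-separated synonym.",
              bad[1] + has_header),
      "format"
    )
  }
  tibble(concept_id = parts[, 1], synonym = parts[, 2])
}

parse_edge_tsv <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort_ontosim(sprintf("%s: empty hierarchy file.", path), "format")
  }
  parts <- stringr::str_split_fixed(lines, "\t", 3)
  start <- if (identical(tolower(parts[1, 1]), "child_id")) 2L else 1L
  if (start > nrow(parts)) {
    abort_ontosim(sprintf("%s: no edges after header.", path), "format")
  }
  body <- parts[seq(start, nrow(parts)), , drop = FALSE]
  bad <- which(body[, 1] == "" | body[, 2] == "")
  if (length(bad) > 0) {
    abort_ontosim(
      sprintf("%s line %d: expected child_id<TAB>parent_id.",
              path, bad[1] + start - 1L),
      "format"
    )
  }
  tibble(child_id = body[, 1], parent_id = body[, 2])
}

parse_obo <- function(lines, path) {
  term_starts <- which(stringr::str_detect(lines, "^\\[Term\\]\\s*$"))
  other_starts <- which(stringr::str_detect(lines, "^\\[") &
                          !stringr::str_detect(lines, "^\\[Term\\]"))
  if (length(term_starts) == 0) {
    abort_ontosim(sprintf("%s: no [Term] stanza found.", path), "format")
  }
  bounds <- sort(c(term_starts, other_starts, length(lines) + 1L))
  edges <- list(); nms <- list(); syns <- list()
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    chunk <- lines[seq(s + 1L, e)]
    get_vals <- function(tag) {
      hit <- stringr::str_starts(chunk, paste0(tag, ":"))
      trimws(sub(paste0("^", tag, ":\\s*"), "", chunk[hit]))
    }
    id <- get_vals("id")
    if (length(id) != 1 || id == "") {
      abort_ontosim(
        sprintf("%s line %d: [Term] stanza without a single id.", path, s),
        "format"
      )
    }
    name <- get_vals("name")
    isa <- get_vals("is_a")
    isa <- trimws(sub("\\s*!.*$", "", isa))      # strip trailing comment
    isa <- isa[nzchar(isa)]
    syn_raw <- get_vals("synonym")
    syn_txt <- stringr::str_match(syn_raw, "^\"([^\"]*)\"")[, 2]
    syn_txt <- syn_txt[!is.na(syn_txt) & nzchar(syn_txt)]
    if (length(isa) > 0) {
      edges[[length(edges) + 1L]] <- tibble(child_id = id, parent_id = isa)
    }
    if (length(name) >= 1) {
      nms[[length(nms) + 1L]] <- tibble(concept_id = id,
                                        preferred_name = name[1])
    }
    if (length(syn_txt) > 0) {
      syns[[length(syns) + 1L]] <- tibble(concept_id = id, synonym = syn_txt)
    }
  }
  if (length(edges) == 0) {
    abort_ontosim(sprintf("%s: no is_a relationships found.", path), "format")
  }
  list(edges = bind_rows(edges), names = bind_rows(nms),
       synonyms = bind_rows(syns))
}

#' Write an ontology to edge-list and synonym TSV files
#'
#' The edge-list format carries no preferred names, so when a concept's name
#' differs from its id the name is written as an additional synonym row:
#' query groups (name + synonyms) then survive a write/read round trip even
#' though the reloaded preferred name falls back to the concept id.
#'
#' @param ont An [ontology()] object.
#' @param path Output path for the `child_id<TAB>parent_id` edge list.
#' @param synonym_path Optional output path for the synonym table.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ont, path, synonym_path = NULL) {
  stopifnot(inherits(ont, "ontology"))
  readr::write_tsv(ont$edges, path)
  if (!is.null(synonym_path)) {
    syn <- tidyr::unnest(
      select(ont$concepts, "concept_id", synonym = "synonyms"),
      "synonym"
    )
    named <- ont$concepts[ont$concepts$preferred_name !=
                            ont$concepts$concept_id, ]
    syn <- distinct(bind_rows(
      tibble(concept_id = named$concept_id, synonym = named$preferred_name),
      syn
    ))
    readr::write_tsv(syn, synonym_path)
  }
  invisible(path)
}

#' Read a report cohort table
#'
#' Expects a tab-separated file `report_id<TAB>diagnosis<TAB>term_ids` where
#' the third column is a semicolon-joined (possibly empty) list of extracted
#' concept ids.
#'
#' @param path Path to the report table.
#' @return A tibble with columns `report_id`, `diagnosis`, and `term_ids`
#'   (list-column of character vectors).
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) {
    abort_ontosim(sprintf("Report file not found: %s", path), "io")
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort_ontosim(sprintf("%s: empty report file.", path), "format")
  }
  parts <- stringr::str_split_fixed(lines, "\t", 3)
  start <- if (identical(tolower(parts[1, 1]), "report_id")) 2L else 1L
  body <- parts[seq(start, nrow(parts)), , drop = FALSE]
  bad <- which(body[, 1] == "" | body[, 2] == "")
  if (length(bad) > 0) {
    abort_ontosim(
      sprintf("%s line %d: expected report_id<TAB>diagnosis<TAB>terms.",
              path, bad[1] + start - 1L),
      "format"
    )
  }
  reports(tibble(
    report_id = body[, 1],
    diagnosis = body[, 2],
    term_ids = lapply(
      stringr::str_split(body[, 3], ";"),
      function(x) x[nzchar(x)]
    )
  ))
}

#' Validate a report cohort
#'
#' Checks report ids are unique and diagnoses non-empty, and normalizes the
#' `term_ids` list-column.
#'
#' @param x Data frame with columns `report_id`, `diagnosis` and `term_ids`
#'   (list of character vectors, or a semicolon-joined character column).
#' @return A validated tibble of reports.
#' @export
reports <- function(x) {
  x <- as_tibble(x)
  need <- c("report_id", "diagnosis", "term_ids")
  if (!all(need %in% names(x))) {
    abort_ontosim("Reports need columns report_id, diagnosis, term_ids.",
                  "format")
  }
  x$report_id <- as.character(x$report_id)
  x$diagnosis <- as.character(x$diagnosis)
  if (is.character(x$term_ids)) {
    x$term_ids <- lapply(stringr::str_split(x$term_ids, ";"),
                         function(v) v[nzchar(v)])
  }
  x$term_ids <- lapply(x$term_ids, function(v) unique(as.character(v)))
  if (anyDuplicated(x$report_id)) {
    abort_ontosim(
      sprintf("Duplicate report id(s): %s.",
              paste(head(unique(x$report_id[duplicated(x$report_id)]), 5),
                    collapse = ", ")),
      "validation"
    )
  }
  if (any(x$diagnosis == "" | is.na(x$diagnosis))) {
    abort_ontosim("Every report needs a non-empty diagnosis label.",
                  "validation")
  }
  x[, need]
}

#' Write a report cohort table
#'
#' @param x A reports tibble (see [reports()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(x, path) {
  x <- reports(x)
  readr::write_tsv(
    tibble(
      report_id = x$report_id,
      diagnosis = x$diagnosis,
      term_ids = purrr::map_chr(x$term_ids, paste, collapse = ";")
    ),
    path
  )
  invisible(path)
}

#' Read an abstract corpus
#'
#' Expects a tab-separated file `abstract_id<TAB>text`, one abstract per line.
#'
#' @param path Path to the corpus file.
#' @return A tibble with columns `abstract_id` and `text`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort_ontosim(sprintf("Corpus file not found: %s", path), "io")
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort_ontosim(sprintf("%s: empty corpus.", path), "format")
  }
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  start <- if (identical(tolower(parts[1, 1]), "abstract_id")) 2L else 1L
  if (start > nrow(parts)) {
    abort_ontosim(sprintf("%s: empty corpus.", path), "format")
  }
  body <- parts[seq(start, nrow(parts)), , drop = FALSE]
  bad <- which(body[, 1] == "" | body[, 2] == "")
  if (length(bad) > 0) {
    abort_ontosim(
      sprintf("%s line %d: expected abstract_id<TAB>text.",
              path, bad[1] + start - 1L),
      "format"
    )
  }
  tibble(abstract_id = body[, 1], text = body[, 2])
}

#' Write an abstract corpus
#'
#' @param corpus Tibble with columns `abstract_id`, `text`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  readr::write_tsv(as_tibble(corpus)[, c("abstract_id", "text")], path)
  invisible(path)
}
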