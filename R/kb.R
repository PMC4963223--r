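#' Disease-symptom knowledge bases
#'
#' A `raredx_kb` object is an in-memory bipartite store associating each
#' disease with its set of phenotypic symptoms, the structure used by
#' symptom-based differential-diagnosis engines. Diseases and symptoms are
#' identified by opaque id strings and carry human-readable names. The
#' object keeps, besides the two vocabularies, a forward index (symptom set
#' per disease) and an inverted index (diseases per symptom) so that a
#' query can be scored against every disease in time proportional to the
#' total posting-list length of its symptoms.
#'
#' @name raredx_kb
#' @keywords internal
NULL

# Construct a raredx_kb from three plain tables. Internal: all loaders and
# the synthetic generator funnel through here so invariants hold in one
# place. `associations` may reference symptom ids absent from `symptoms`;
# those are added to the vocabulary with NA names and flagged by
# validate_kb() as dangling references.
kb_from_tables <- function(diseases, symptoms, associations) {
  diseases <- data.frame(
    disease_id = as.character(diseases$disease_id),
    disease_name = as.character(diseases$disease_name),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(diseases$disease_id)) {
    abort_data("duplicate disease ids: ",
               paste(unique(diseases$disease_id[duplicated(diseases$disease_id)]),
                     collapse = ", "))
  }
  symptoms <- data.frame(
    symptom_id = as.character(symptoms$symptom_id),
    symptom_name = as.character(symptoms$symptom_name),
    stringsAsFactors = FALSE
  )
  symptoms <- symptoms[!duplicated(symptoms$symptom_id), , drop = FALSE]
  dangling <- setdiff(unique(as.character(associations$symptom_id)),
                      symptoms$symptom_id)
  if (length(dangling)) {
    symptoms <- rbind(symptoms, data.frame(symptom_id = dangling,
                                           symptom_name = NA_character_,
                                           stringsAsFactors = FALSE))
  }
  diseases <- diseases[order(diseases$disease_id), , drop = FALSE]
  symptoms <- symptoms[order(symptoms$symptom_id), , drop = FALSE]
  rownames(diseases) <- rownames(symptoms) <- NULL

  di <- match(as.character(associations$disease_id), diseases$disease_id)
  if (anyNA(di)) {
    abort_data("associations reference unknown disease ids: ",
               paste(unique(associations$disease_id[is.na(di)]), collapse = ", "))
  }
  si <- match(as.character(associations$symptom_id), symptoms$symptom_id)
  dup <- duplicated(cbind(di, si))
  if (any(dup)) {
    warning(sum(dup), " duplicate disease-symptom association(s) dropped",
            call. = FALSE)
    di <- di[!dup]; si <- si[!dup]
  }
  nd <- nrow(diseases); ns <- nrow(symptoms)
  disease_symptoms <- lapply(
    split(si, factor(di, levels = seq_len(nd))),
    function(x) sort.int(x)
  )
  names(disease_symptoms) <- NULL
  symptom_diseases <- lapply(
    split(di, factor(si, levels = seq_len(ns))),
    function(x) sort.int(x)
  )
  names(symptom_diseases) <- NULL
  structure(
    list(diseases = diseases, symptoms = symptoms,
         disease_symptoms = disease_symptoms,
         symptom_diseases = symptom_diseases,
         sizes = lengths(disease_symptoms)),
    class = "raredx_kb"
  )
}

#' Build a knowledge base from a list of symptom-id sets
#'
#' Convenience constructor used in examples, tests and the acceptance
#' script: each list element is a disease, named by its id, containing the
#' character vector of its symptom ids. Names default to the ids.
#'
#' @param sets Named list of character vectors of symptom ids.
#' @param disease_names Optional character vector of labels, parallel to
#'   `sets`; defaults to the disease ids.
#' @param symptom_names Optional named character vector mapping symptom id
#'   to label; defaults to the ids.
#' @return A `raredx_kb`.
#' @examples
#' kb <- kb_from_sets(list(D1 = c("a", "b"), D2 = c("b", "c"), D3 = "d"))
#' kb
#' @export
kb_from_sets <- function(sets, disease_names = NULL, symptom_names = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a fully named list of symptom-id vectors", call. = FALSE)
  }
  ids <- names(sets)
  if (is.null(disease_names)) disease_names <- ids
  sym_ids <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(symptom_names)) {
    symptom_names <- stats::setNames(sym_ids, sym_ids)
  }
  assoc <- data.frame(
    disease_id = rep(ids, lengths(sets)),
    symptom_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  kb_from_tables(
    data.frame(disease_id = ids, disease_name = disease_names,
               stringsAsFactors = FALSE),
    data.frame(symptom_id = sym_ids,
               symptom_name = unname(symptom_names[sym_ids]),
               stringsAsFactors = FALSE),
    assoc
  )
}

KB_TSV_HEADER <- c("disease_id", "disease_name", "symptom_id", "symptom_name")

#' Load a disease-symptom knowledge base
#'
#' Reads a knowledge base from the canonical long-format TSV dialect (one
#' disease-symptom association per row, header
#' `disease_id  disease_name  symptom_id  symptom_name`, no quoting) or
#' from the nested JSON dialect (`symptoms`: list of id/name records;
#' `diseases`: list of id/name/symptom_ids records). The order of
#' associations in the file does not affect the result; duplicate
#' associations are dropped with a warning (a disease's symptoms form a
#' set).
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"json"`; by default inferred from the file
#'   extension, falling back to TSV.
#' @return A validated `raredx_kb`. A warning is emitted if
#'   [validate_kb()] reports problems (empty symptom sets, dangling
#'   symptom references, duplicate symptom sets).
#' @seealso [write_kb()], [validate_kb()]
#' @export
load_kb <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (!file.exists(path)) abort_data("knowledge base file not found: ", path)
  kb <- if (format == "tsv") load_kb_tsv(path) else load_kb_json(path)
  rep <- validate_kb(kb)
  if (!rep$ok) {
    warning("loaded knowledge base has validation problems; see validate_kb()",
            call. = FALSE)
  }
  kb
}

load_kb_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    abort_data("empty knowledge base file: ", path)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, KB_TSV_HEADER)) {
    abort_data("line 1: expected header '",
               paste(KB_TSV_HEADER, collapse = "\\t"), "'")
  }
  if (length(lines) == 1L) abort_data("no associations in file: ", path)
  nf <- utils::count.fields(textConnection(lines), sep = "\t", quote = "")
  bad <- which(is.na(nf) | nf != 4L)
  bad <- setdiff(bad, 1L)
  if (length(bad)) {
    abort_data("malformed row(s) at line(s) ",
               paste(bad, collapse = ", "), ": expected 4 tab-separated fields")
  }
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                           quote = "", colClasses = "character",
                           stringsAsFactors = FALSE)
  diseases <- tab[!duplicated(tab$disease_id),
                  c("disease_id", "disease_name"), drop = FALSE]
  symptoms <- tab[!duplicated(tab$symptom_id),
                  c("symptom_id", "symptom_name"), drop = FALSE]
  kb_from_tables(diseases, symptoms,
                 tab[, c("disease_id", "symptom_id"), drop = FALSE])
}

load_kb_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort_data("malformed JSON in ", path, ": ", conditionMessage(e))
                  })
  if (!is.list(obj) || !all(c("symptoms", "diseases") %in% names(obj))) {
    abort_data("JSON knowledge base must have 'symptoms' and 'diseases' keys")
  }
  sym <- obj$symptoms
  dis <- obj$diseases
  if (NROW(dis) == 0L) abort_data("empty knowledge base file: ", path)
  symptoms <- data.frame(symptom_id = as.character(sym$id),
                         symptom_name = as.character(sym$name),
                         stringsAsFactors = FALSE)
  diseases <- data.frame(disease_id = as.character(dis$id),
                         disease_name = as.character(dis$name),
                         stringsAsFactors = FALSE)
  sets <- dis$symptom_ids
  if (is.null(sets)) abort_data("JSON diseases must carry 'symptom_ids'")
  assoc <- data.frame(
    disease_id = rep(diseases$disease_id, vapply(sets, length, 0L)),
    symptom_id = as.character(unlist(sets, use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  kb_from_tables(diseases, symptoms, assoc)
}

#' Validate a knowledge base
#'
#' Reports, without modifying the store: diseases with empty symptom sets,
#' dangling symptom references (symptom ids used by a disease but not
#' declared in the vocabulary), and pairs of diseases with identical
#' symptom sets. Distinct symptom sets are required for the no-noise
#' perfect-recovery property of the benchmark (two diseases with the same
#' set are inherently indistinguishable to a set-similarity score).
#'
#' @param kb A `raredx_kb`.
#' @return A `raredx_kb_report` list with elements `empty_diseases`
#'   (character ids), `dangling_symptoms` (character ids with no declared
#'   name), `duplicate_set_pairs` (two-column data frame of disease-id
#'   pairs) and `ok` (logical).
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "raredx_kb"))
  empty <- kb$diseases$disease_id[kb$sizes == 0L]
  dangling <- kb$symptoms$symptom_id[is.na(kb$symptoms$symptom_name)]
  keys <- vapply(kb$disease_symptoms, paste, "", collapse = "\r")
  dup_pairs <- data.frame(disease_a = character(), disease_b = character(),
                          stringsAsFactors = FALSE)
  nz_keys <- keys[kb$sizes > 0L]
  if (anyDuplicated(nz_keys)) {
    grp <- split(kb$diseases$disease_id[kb$sizes > 0L], nz_keys)
    grp <- grp[lengths(grp) > 1L]
    for (g in grp) {
      cmb <- utils::combn(sort(g), 2L)
      dup_pairs <- rbind(dup_pairs,
                         data.frame(disease_a = cmb[1L, ], disease_b = cmb[2L, ],
                                    stringsAsFactors = FALSE))
    }
  }
  structure(
    list(empty_diseases = empty,
         dangling_symptoms = dangling,
         duplicate_set_pairs = dup_pairs,
         ok = length(empty) == 0L && length(dangling) == 0L &&
           nrow(dup_pairs) == 0L),
    class = "raredx_kb_report"
  )
}

#' @export
print.raredx_kb_report <- function(x, ...) {
  if (x$ok) {
    cat("knowledge base OK\n")
    return(invisible(x))
  }
  if (length(x$empty_diseases)) {
    cat("diseases with empty symptom sets:",
        paste(x$empty_diseases, collapse = ", "), "\n")
  }
  if (length(x$dangling_symptoms)) {
    cat("dangling symptom references:",
        paste(x$dangling_symptoms, collapse = ", "), "\n")
  }
  if (nrow(x$duplicate_set_pairs)) {
    cat(nrow(x$duplicate_set_pairs), "duplicate symptom-set pair(s), e.g.",
        x$duplicate_set_pairs$disease_a[1L], "/",
        x$duplicate_set_pairs$disease_b[1L], "\n")
  }
  invisible(x)
}

#' Write a knowledge base to disk
#'
#' Emits the canonical TSV dialect with rows sorted by (disease id,
#' symptom id), or the nested JSON dialect with sorted records, so the
#' output is byte-stable across runs and re-loadable via [load_kb()] to an
#' equal knowledge base. Refuses to write a knowledge base that fails
#' [validate_kb()] for empty symptom sets or dangling references.
#'
#' @inheritParams load_kb
#' @param kb A `raredx_kb`.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(kb, "raredx_kb"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  rep <- validate_kb(kb)
  if (length(rep$empty_diseases) || length(rep$dangling_symptoms)) {
    abort_data("refusing to write invalid knowledge base (",
               length(rep$empty_diseases), " empty disease set(s), ",
               length(rep$dangling_symptoms), " dangling symptom reference(s))")
  }
  assoc <- kb_associations(kb)
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(KB_TSV_HEADER, collapse = "\t"), con, sep = "\n")
    writeLines(paste(assoc$disease_id, assoc$disease_name,
                     assoc$symptom_id, assoc$symptom_name, sep = "\t"),
               con, sep = "\n")
  } else {
    obj <- list(
      symptoms = kb$symptoms[, c("symptom_id", "symptom_name")],
      diseases = data.frame(id = kb$diseases$disease_id,
                            name = kb$diseases$disease_name,
                            stringsAsFactors = FALSE)
    )
    names(obj$symptoms) <- c("id", "name")
    obj$diseases$symptom_ids <- lapply(kb$disease_symptoms,
                                       function(i) kb$symptoms$symptom_id[i])
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

# Canonical long-format association table, sorted by (disease_id,
# symptom_id). Two knowledge bases are equal iff these tables are equal.
kb_associations <- function(kb) {
  data.frame(
    disease_id = rep(kb$diseases$disease_id, kb$sizes),
    disease_name = rep(kb$diseases$disease_name, kb$sizes),
    symptom_id = kb$symptoms$symptom_id[unlist(kb$disease_symptoms,
                                               use.names = FALSE)],
    symptom_name = kb$symptoms$symptom_name[unlist(kb$disease_symptoms,
                                                   use.names = FALSE)],
    stringsAsFactors = FALSE
  )
}

#' Symptom set of one disease
#'
#' @param kb A `raredx_kb`.
#' @param disease_id Disease id string.
#' @return Character vector of symptom ids.
#' @export
kb_disease_symptoms <- function(kb, disease_id) {
  i <- match(disease_id, kb$diseases$disease_id)
  if (is.na(i)) abort_data("unknown disease id: ", disease_id)
  kb$symptoms$symptom_id[kb$disease_symptoms[[i]]]
}

# MD5 of the canonical TSV serialization; recorded in output metadata so
# results can be tied to the exact knowledge base that produced them.
kb_checksum <- function(kb) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_kb(kb, tmp, "tsv")
  unname(tools::md5sum(tmp))
}

#' @export
print.raredx_kb <- function(x, ...) {
  cat("<raredx_kb> ", nrow(x$diseases), " diseases, ",
      nrow(x$symptoms), " symptoms, ",
      sum(x$sizes), " associations\n", sep = "")
  if (length(x$sizes)) {
    cat("  symptoms per disease: min ", min(x$sizes), ", median ",
        stats::median(x$sizes), ", max ", max(x$sizes), "\n", sep = "")
  }
  invisible(x)
}
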