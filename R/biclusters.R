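#' Construct a bicluster record
#'
#' A bicluster is a non-empty set of samples together with a non-empty set of
#' genes whose sub-matrix shows coherent (here: elevated) expression, plus
#' provenance of the fixed-point search that produced it.
#'
#' @param id character identifier, unique within a set.
#' @param samples character vector of sample ids (non-empty, deduplicated).
#' @param genes character vector of gene ids (non-empty, deduplicated).
#' @param seed_group integer index of the seed group the converging seed
#'   belonged to, or `NA` for imported records.
#' @param t_G,t_C gene- and sample-axis thresholds (score-sd units) in force
#'   when the record was produced, or `NA`.
#' @param n_iterations number of ISA iterations to convergence, or `NA`.
#' @param converged logical convergence flag.
#' @return an object of class `"bicluster"`.
#' @export
bicluster <- function(id, samples, genes, seed_group = NA_integer_,
                      t_G = NA_real_, t_C = NA_real_,
                      n_iterations = NA_integer_, converged = NA) {
  samples <- unique(as.character(samples))
  genes <- unique(as.character(genes))
  if (length(samples) == 0L) stop("bicluster '", id, "' has an empty sample set")
  if (length(genes) == 0L) stop("bicluster '", id, "' has an empty gene set")
  structure(list(id = as.character(id), samples = samples, genes = genes,
                 seed_group = as.integer(seed_group), t_G = as.numeric(t_G),
                 t_C = as.numeric(t_C), n_iterations = as.integer(n_iterations),
                 converged = converged),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster '%s': %d samples x %d genes (seed group %s, t_G=%s, t_C=%s, %s)\n",
              x$id, length(x$samples), length(x$genes),
              ifelse(is.na(x$seed_group), "-", x$seed_group),
              ifelse(is.na(x$t_G), "-", format(x$t_G)),
              ifelse(is.na(x$t_C), "-", format(x$t_C)),
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Construct a bicluster set
#'
#' @param records list of [bicluster()] objects.
#' @param parameters list of run parameters to store alongside the records
#'   (serialized verbatim).
#' @return an object of class `"bicluster_set"` (a list with elements
#'   `records` and `parameters`).
#' @export
bicluster_set <- function(records = list(), parameters = list()) {
  stopifnot(is.list(records))
  for (r in records) {
    if (!inherits(r, "bicluster")) stop("all records must be bicluster objects")
  }
  ids <- vapply(records, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicated bicluster ids")
  structure(list(records = records, parameters = parameters), class = "bicluster_set")
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat(sprintf("bicluster_set with %d records\n", length(x$records)))
  for (r in x$records) print(r)
  invisible(x)
}

#' @export
length.bicluster_set <- function(x) length(x$records)

BICLUSTER_SCHEMA_VERSION <- 1L

#' Write a bicluster set to JSON (and optionally a flat TSV)
#'
#' The JSON document carries a schema version, the run parameters and one
#' object per record; the round trip through [read_biclusters()] is lossless.
#' The optional TSV is a long table `bicluster_id, axis, id` with
#' `axis` in `{sample, gene}`, convenient for spreadsheets.
#'
#' @param bs a [bicluster_set()].
#' @param path output JSON path.
#' @param tsv optional path for the flat TSV companion.
#' @export
write_biclusters <- function(bs, path, tsv = NULL) {
  stopifnot(inherits(bs, "bicluster_set"))
  doc <- list(
    schema_version = BICLUSTER_SCHEMA_VERSION,
    parameters = bs$parameters,
    records = lapply(bs$records, function(r) {
      list(id = r$id, samples = as.list(r$samples), genes = as.list(r$genes),
           seed_group = r$seed_group, t_G = r$t_G, t_C = r$t_C,
           n_iterations = r$n_iterations, converged = r$converged)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (!is.null(tsv)) {
    long <- do.call(rbind, lapply(bs$records, function(r) {
      rbind(data.frame(bicluster_id = r$id, axis = "sample", id = r$samples),
            data.frame(bicluster_id = r$id, axis = "gene", id = r$genes))
    }))
    if (is.null(long)) long <- data.frame(bicluster_id = character(), axis = character(), id = character())
    utils::write.table(long, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a bicluster set from JSON
#'
#' Accepts any file following the schema written by [write_biclusters()],
#' including bicluster sets produced by other tools, which makes
#' cross-method comparison with [effective_number()] and [capture_table()]
#' possible without reimplementing those tools.
#'
#' @param path JSON path.
#' @return a [bicluster_set()].
#' @export
read_biclusters <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != BICLUSTER_SCHEMA_VERSION) {
    stop("unknown bicluster schema version: ", format(doc$schema_version))
  }
  records <- lapply(doc$records, function(r) {
    bicluster(id = r$id,
              samples = unlist(r$samples, use.names = FALSE),
              genes = unlist(r$genes, use.names = FALSE),
              seed_group = if (is.null(r$seed_group)) NA_integer_ else r$seed_group,
              t_G = if (is.null(r$t_G)) NA_real_ else r$t_G,
              t_C = if (is.null(r$t_C)) NA_real_ else r$t_C,
              n_iterations = if (is.null(r$n_iterations)) NA_integer_ else r$n_iterations,
              converged = if (is.null(r$converged)) NA else r$converged)
  })
  params <- doc$parameters
  if (is.null(params)) params <- list()
  bicluster_set(records, parameters = params)
}
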