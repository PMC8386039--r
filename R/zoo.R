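#' Model identifiers
#'
#' A model is identified by its class (embedding or celltype), organism,
#' organ, topology id (kind plus hyperparameter version, e.g. `"mlp-0.1"`),
#' feature-space tag and output version. The identifier serialises to a
#' unique, filesystem-safe string
#' `class_organism_organ_topology_featurespace_vVERSION` and round-trips
#' through [parse_model_id()]. Fields may contain letters, digits, dots
#' and dashes only (the underscore is the field separator).
#'
#' @param model_class `"embedding"` or `"celltype"`
#' @param organism organism tag
#' @param organ organ tag
#' @param topology topology id, `kind-version`
#' @param feature_space feature-space tag (assembly plus gene-subset name)
#' @param output_version dotted numeric parameter version, e.g. `"1.0"`
#' @return a `model_id`
#' @examples
#' id <- model_id("celltype", "mouse", "spleen", "mlp-0.1", "GRCm38.102-pc", "1.0")
#' format(id)
#' parse_model_id(format(id))
#' @export
model_id <- function(model_class = c("embedding", "celltype"),
                     organism, organ, topology, feature_space,
                     output_version = "1.0") {
  model_class <- match.arg(model_class)
  fields <- list(model_class = model_class, organism = organism,
                 organ = organ, topology = topology,
                 feature_space = feature_space,
                 output_version = output_version)
  for (nm in names(fields)[-1L]) {
    if (!grepl("^[A-Za-z0-9.-]+$", fields[[nm]])) {
      oz_stop("schema_error",
              "model id field '%s' ('%s') may only contain [A-Za-z0-9.-]",
              nm, fields[[nm]])
    }
  }
  structure(fields, class = "model_id")
}

#' @export
format.model_id <- function(x, ...) {
  paste(x$model_class, x$organism, x$organ, x$topology, x$feature_space,
        paste0("v", x$output_version), sep = "_")
}

#' @export
print.model_id <- function(x, ...) {
  cat("<model_id>", format(x), "\n")
  invisible(x)
}

#' @rdname model_id
#' @param id_string a serialised model id
#' @export
parse_model_id <- function(id_string) {
  parts <- strsplit(id_string, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 6L || !startsWith(parts[6L], "v")) {
    oz_stop("schema_error", "cannot parse model id '%s'", id_string)
  }
  model_id(parts[1L], parts[2L], parts[3L], parts[4L], parts[5L],
           sub("^v", "", parts[6L]))
}

record_dirname <- function(id, provider, data_id, optim_id) {
  for (f in c(provider, data_id, optim_id)) {
    if (!grepl("^[A-Za-z0-9.-]+$", f)) {
      oz_stop("schema_error", "record field '%s' may only contain [A-Za-z0-9.-]", f)
    }
  }
  paste(format(id), provider, data_id, optim_id, sep = "__")
}

# Compare dotted numeric version strings; returns -1/0/1.
compare_versions <- function(a, b) {
  pa <- as.integer(strsplit(a, ".", fixed = TRUE)[[1L]])
  pb <- as.integer(strsplit(b, ".", fixed = TRUE)[[1L]])
  n <- max(length(pa), length(pb))
  pa <- c(pa, rep(0L, n - length(pa)))
  pb <- c(pb, rep(0L, n - length(pb)))
  d <- pa - pb
  nz <- which(d != 0L)
  if (!length(nz)) 0L else sign(d[nz[1L]])
}

model_array_shapes <- function(model) {
  lapply(flatten_params(model$params), dim_or_length)
}
dim_or_length <- function(x) dim(x) %||% length(x)

validate_topology <- function(model) {
  spec <- model$spec
  set.seed(0L)
  ref <- if (inherits(model, "ontozoo_classifier")) {
    init_classifier_params(spec)
  } else {
    init_embedding_params(spec)
  }
  ref_shapes <- lapply(flatten_params(ref), dim_or_length)
  got_shapes <- model_array_shapes(model)
  for (nm in union(names(ref_shapes), names(got_shapes))) {
    if (nm %in% c("W_train")) next
    if (!identical(as.integer(ref_shapes[[nm]] %||% -1L),
                   as.integer(got_shapes[[nm]] %||% -2L))) {
      oz_stop("topology_mismatch_error",
              "array '%s' does not match the declared topology (expected %s, got %s)",
              nm, paste(ref_shapes[[nm]] %||% "absent", collapse = "x"),
              paste(got_shapes[[nm]] %||% "absent", collapse = "x"))
    }
  }
  invisible(TRUE)
}

#' Publish a fitted model to a parameter store
#'
#' Writes a write-once parameter record: a directory named by the model id
#' plus provider, training-data and optimization descriptors, holding
#' `meta.json` (identifier fields, checksum, timestamp) and the array
#' payload. Re-publishing the same key fails; bump the id's
#' `output_version` instead. Array shapes are validated against the
#' topology declared by the model's spec before anything is written.
#'
#' @param store store directory (created if missing)
#' @param model an `ontozoo_classifier` or `ontozoo_embedding`
#' @param id a [model_id()]
#' @param provider organization that trained the parameters
#' @param data_id training-data descriptor
#' @param optim_id optimization-hyperparameter descriptor
#' @return invisibly, the record directory
#' @seealso [load_model()], [query_store()]
#' @export
publish_model <- function(store, model, id, provider,
                          data_id = "d1", optim_id = "o1") {
  stopifnot(inherits(id, "model_id"))
  if (!inherits(model, c("ontozoo_classifier", "ontozoo_embedding"))) {
    oz_stop("domain_error", "only fitted ontozoo models can be published")
  }
  validate_topology(model)
  dir.create(store, recursive = TRUE, showWarnings = FALSE)
  rec_dir <- file.path(store, record_dirname(id, provider, data_id, optim_id))
  if (dir.exists(rec_dir)) {
    oz_stop("version_conflict_error",
            "record '%s' already exists; parameter versions are write-once",
            basename(rec_dir))
  }
  dir.create(rec_dir)
  payload <- file.path(rec_dir, "params.rds")
  saveRDS(model, payload, version = 3)
  meta <- list(id = unclass(id), id_string = format(id), provider = provider,
               data_id = data_id, optim_id = optim_id,
               checksum = unname(tools::md5sum(payload)),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               payload = "params.rds")
  jsonlite::write_json(meta, file.path(rec_dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec_dir)
}

#' Load a published model, verifying its checksum
#'
#' @param store store directory
#' @param id a [model_id()] or serialised id string
#' @param provider,data_id,optim_id record key fields
#' @return the stored model, bit-identical to what was published
#' @export
load_model <- function(store, id, provider, data_id = "d1", optim_id = "o1") {
  if (is.character(id)) id <- parse_model_id(id)
  rec_dir <- file.path(store, record_dirname(id, provider, data_id, optim_id))
  meta_path <- file.path(rec_dir, "meta.json")
  if (!file.exists(meta_path)) {
    oz_stop("schema_error", "no record '%s' in store", basename(rec_dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  payload <- file.path(rec_dir, meta$payload)
  actual <- unname(tools::md5sum(payload))
  if (!identical(actual, meta$checksum)) {
    oz_stop("integrity_error",
            "checksum mismatch for '%s': payload is corrupted", basename(rec_dir))
  }
  readRDS(payload)
}

#' Query a parameter store
#'
#' Lists records matching the given fields (all optional), sorted by
#' output version descending then by id string, independent of filesystem
#' enumeration order.
#'
#' @param store store directory
#' @param ... filters over `model_class`, `organism`, `organ`, `topology`,
#'   `feature_space`, `output_version`, `provider`, `data_id`, `optim_id`
#' @return data.frame of matching records (possibly empty)
#' @export
query_store <- function(store, ...) {
  query <- list(...)
  known <- c("model_class", "organism", "organ", "topology", "feature_space",
             "output_version", "provider", "data_id", "optim_id")
  unknown <- setdiff(names(query), known)
  if (length(unknown)) oz_stop("schema_error", "unknown query field '%s'", unknown[1L])
  metas <- sort(list.files(store, pattern = "^meta\\.json$", recursive = TRUE,
                           full.names = TRUE))
  rows <- lapply(metas, function(mp) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    data.frame(id_string = meta$id_string,
               model_class = meta$id$model_class, organism = meta$id$organism,
               organ = meta$id$organ, topology = meta$id$topology,
               feature_space = meta$id$feature_space,
               output_version = meta$id$output_version,
               provider = meta$provider, data_id = meta$data_id,
               optim_id = meta$optim_id, checksum = meta$checksum,
               created = meta$created, path = dirname(mp))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_string = character(), model_class = character(),
               organism = character(), organ = character(),
               topology = character(), feature_space = character(),
               output_version = character(), provider = character(),
               data_id = character(), optim_id = character(),
               checksum = character(), created = character(),
               path = character())
  for (key in names(query)) df <- df[df[[key]] %in% query[[key]], , drop = FALSE]
  if (nrow(df) > 1L) {
    vkey <- vapply(df$output_version, function(v) {
      p <- as.integer(strsplit(v, ".", fixed = TRUE)[[1L]])
      p <- c(p, rep(0L, 4L - length(p)))[1:4]
      sprintf("%09d.%09d.%09d.%09d", p[1], p[2], p[3], p[4])
    }, "")
    df <- df[order(vkey, df$id_string, decreasing = c(TRUE, FALSE),
                   method = "radix"), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
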