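# Sequence and label I/O, dataset assembly, model bundle persistence.

BUNDLE_FORMAT <- "enfusion-bundle/1"

#' Construct a validated sequence dataset
#'
#' A `seq_dataset` is the package's sample container: an ordered set of
#' fixed-alphabet DNA fragments with unique ids and, optionally, parallel
#' binary labels (1 = enhancer, 0 = non-enhancer).
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of sequences over the uppercase alphabet
#'   A/C/G/T.  Lowercase input is uppercased; any other character is an
#'   error (the feature encoders define no semantics for ambiguity codes).
#' @param label Optional integer vector of 0/1 labels, parallel to `seq`.
#' @return An object of class `seq_dataset` with fields `id`, `seq`,
#'   `label`.
#' @export
seq_dataset <- function(id, seq, label = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop_enfusion("id and seq must have equal length")
  }
  if (anyDuplicated(id)) {
    stop_enfusion("duplicate sequence ids: ",
                  paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad <- regexpr("[^ACGT]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop_enfusion(
      "sequence '", id[i], "' contains invalid character '",
      substr(seq[i], bad[i], bad[i]), "' at position ", bad[i],
      "; only A/C/G/T are allowed",
      class = "enfusion_validation_error"
    )
  }
  if (any(nchar(seq) < 1L)) {
    stop_enfusion("empty sequence: ", id[which(nchar(seq) < 1L)[1L]])
  }
  if (!is.null(label)) {
    label <- as.integer(label)
    if (length(label) != length(seq)) {
      stop_enfusion("label vector must be parallel to sequences")
    }
    if (anyNA(label) || !all(label %in% c(0L, 1L))) {
      stop_enfusion("labels must be binary 0/1")
    }
  }
  structure(list(id = id, seq = seq, label = label), class = "seq_dataset")
}

#' @export
length.seq_dataset <- function(x) length(x$id)

#' @export
`[.seq_dataset` <- function(x, i) {
  seq_dataset(x$id[i], x$seq[i], if (is.null(x$label)) NULL else x$label[i])
}

#' @export
print.seq_dataset <- function(x, ...) {
  cat("<seq_dataset> ", length(x), " sequences", sep = "")
  if (!is.null(x$label)) {
    cat(" (", sum(x$label == 1L), " positive / ",
        sum(x$label == 0L), " negative)", sep = "")
  }
  lens <- range(nchar(x$seq))
  cat(", lengths ", lens[1L],
      if (lens[2L] != lens[1L]) paste0("-", lens[2L]), " bp\n", sep = "")
  invisible(x)
}

#' Read DNA sequences from a FASTA file
#'
#' Parses a multi-record FASTA file (wrapped or unwrapped lines) into a
#' [seq_dataset()].  Record order is preserved, residues are uppercased and
#' any residue outside A/C/G/T (including ambiguity codes such as N) is
#' rejected with the offending record named.
#'
#' @param path Path to a FASTA file.
#' @return A [seq_dataset()] without labels.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_enfusion("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop_enfusion("malformed FASTA in '", path, "': ", conditionMessage(e))
    }
  )
  if (length(set) == 0L) stop_enfusion("no FASTA records in '", path, "'")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  seq_dataset(ids, as.character(set))
}

#' Write a sequence dataset to FASTA
#'
#' @param dataset A [seq_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "seq_dataset"))
  writeLines(paste0(">", dataset$id, "\n", dataset$seq), path)
  invisible(path)
}

#' Read a two-column tab-separated label map
#'
#' Expected header `id<TAB>label` with labels in \{0, 1\}; supports
#' single-FASTA workflows where labels are not implied by file of origin.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector of labels, names = ids.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop_enfusion("label file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!identical(colnames(tab)[1:2], c("id", "label"))) {
    stop_enfusion("label map must have header 'id<TAB>label', found: ",
                  paste(colnames(tab), collapse = ", "))
  }
  lab <- suppressWarnings(as.integer(tab$label))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
    stop_enfusion("labels must be 0 or 1")
  }
  if (anyDuplicated(tab$id)) stop_enfusion("duplicate ids in label map")
  stats::setNames(lab, tab$id)
}

#' Attach labels from a label map to a dataset
#'
#' @param dataset A [seq_dataset()].
#' @param labels Named vector as returned by [read_label_map()].
#' @return The dataset with labels attached.
#' @export
set_labels <- function(dataset, labels) {
  stopifnot(inherits(dataset, "seq_dataset"))
  missing <- setdiff(dataset$id, names(labels))
  if (length(missing)) {
    stop_enfusion("no label for id(s): ", paste(utils::head(missing, 3), collapse = ", "))
  }
  seq_dataset(dataset$id, dataset$seq, unname(labels[dataset$id]))
}

#' Merge positive and negative sequence sets into one labelled dataset
#'
#' Positives (e.g. strong and weak enhancers already pooled) come first with
#' label 1, negatives follow with label 0.  Ids shared between the two
#' inputs are disambiguated with `pos_`/`neg_` prefixes.
#'
#' @param positives,negatives [seq_dataset()] objects (either may be empty,
#'   but not both).
#' @return A labelled [seq_dataset()].
#' @export
assemble_dataset <- function(positives, negatives) {
  stopifnot(inherits(positives, "seq_dataset"), inherits(negatives, "seq_dataset"))
  if (length(positives) == 0L && length(negatives) == 0L) {
    stop_enfusion("both sequence sets are empty")
  }
  pid <- positives$id
  nid <- negatives$id
  if (length(intersect(pid, nid))) {
    pid <- paste0("pos_", pid)
    nid <- paste0("neg_", nid)
  }
  seq_dataset(
    c(pid, nid),
    c(positives$seq, negatives$seq),
    c(rep(1L, length(positives)), rep(0L, length(negatives)))
  )
}

#' Save a fitted pipeline model to a directory
#'
#' The bundle is a directory holding a JSON manifest (format version tag,
#' configuration snapshot, seeds) plus one serialized file per fitted
#' component, and round-trips through [load_model()] with bitwise-identical
#' predictions.
#'
#' @param model A fitted pipeline model from [train_pipeline()].
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "enfusion_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = BUNDLE_FORMAT,
    config = model$config,
    seed = model$seed,
    components = c("selector", "embedder", "seqnet", "ensemble"),
    feature_names = model$feature_names
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  for (comp in manifest$components) {
    saveRDS(model[[comp]], file.path(dir, paste0(comp, ".rds")))
  }
  # exact configuration object (the manifest JSON is a readable copy)
  saveRDS(model$config, file.path(dir, "config.rds"))
  invisible(dir)
}

#' Load a pipeline model saved by [save_model()]
#'
#' @param dir Bundle directory.
#' @return An `enfusion_model`.
#' @export
load_model <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop_enfusion("no model manifest in '", dir, "': missing manifest.json")
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(manifest$format, BUNDLE_FORMAT)) {
    stop_enfusion("incompatible bundle format '", manifest$format,
                  "' (expected '", BUNDLE_FORMAT, "')",
                  class = "enfusion_version_error")
  }
  comps <- lapply(manifest$components, function(comp) {
    fp <- file.path(dir, paste0(comp, ".rds"))
    if (!file.exists(fp)) stop_enfusion("bundle missing component: ", comp)
    readRDS(fp)
  })
  names(comps) <- manifest$components
  cfg_path <- file.path(dir, "config.rds")
  config <- if (file.exists(cfg_path)) readRDS(cfg_path) else manifest$config
  structure(
    c(comps, list(config = config, seed = manifest$seed,
                  feature_names = manifest$feature_names)),
    class = "enfusion_model"
  )
}
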