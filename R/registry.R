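# Descriptor registry: the ordered list of descriptor specs that defines the
# feature envelope. The default registry has exactly 58 specs totaling exactly
# 4335 values: 22 named descriptor families plus 36 single-property AAindex
# autocorrelation descriptors of 32 values each.

registry_spec <- function(type, size, params = list()) {
  tibble::tibble(type = type, size = as.integer(size), params = list(params))
}

#' Default descriptor registry
#'
#' The package's standard encoding envelope: 58 descriptor types producing a
#' 4335-value feature vector per peptide. Sizes of the named families are
#' fixed (AAC 20, DPC 400, GAAC 5, GDPC 25, CKSAAP 1200 with gaps 0..2,
#' CKSAAGP 150 with gaps 0..5, APAAC 30, PAAC 25, SEP 1, SER 20, DDE 400,
#' CTriad 343, CTDC 39, CTDT 39, CTDD 195, DDR 20, length 1, Ez 30, Z3 30,
#' Z5 75, Cougar 30, ABHPRK 105); the remaining 36 specs are AAindex
#' single-property autocorrelation descriptors (32 values each).
#'
#' @return An `aap_registry` tibble with columns `type`, `size`, `params`.
#' @examples
#' reg <- default_registry()
#' nrow(reg)        # 58
#' sum(reg$size)    # 4335
#' @export
default_registry <- function() {
  specs <- dplyr::bind_rows(
    registry_spec("length",  1),
    registry_spec("AAC",    20),
    registry_spec("DPC",   400),
    registry_spec("GAAC",    5),
    registry_spec("GDPC",   25),
    registry_spec("CKSAAP", 1200, list(kmax = 2)),
    registry_spec("CKSAAGP", 150, list(kmax = 5)),
    registry_spec("APAAC",   30, list(lambda = 5, w = 0.05)),
    registry_spec("PAAC",    25, list(lambda = 5, w = 0.05)),
    registry_spec("SEP",      1),
    registry_spec("SER",     20),
    registry_spec("DDE",    400),
    registry_spec("CTriad", 343),
    registry_spec("CTDC",    39),
    registry_spec("CTDT",    39),
    registry_spec("CTDD",   195),
    registry_spec("DDR",     20),
    registry_spec("Ez",      30, list(lags = 1:10)),
    registry_spec("Z3",      30, list(lags = 1:10)),
    registry_spec("Z5",      75, list(lags = 1:15)),
    registry_spec("Cougar",  30, list(lags = 1:10)),
    registry_spec("ABHPRK", 105, list(lags = 1:15)),
    dplyr::bind_rows(lapply(AAINDEX_SET, function(acc) {
      registry_spec(paste0("AAindex.", acc), 32,
                    list(accession = acc, lags = 1:10))
    }))
  )
  structure(specs, class = c("aap_registry", class(specs)))
}

#' Restrict a registry to selected descriptor types
#'
#' @param registry An `aap_registry` tibble.
#' @param types Character vector of descriptor type names to keep.
#' @return The restricted registry, in original order.
#' @export
registry_subset <- function(registry, types) {
  unknown <- setdiff(types, registry$type)
  if (length(unknown)) {
    stop("unknown descriptor type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- registry[registry$type %in% types, , drop = FALSE]
  structure(out, class = unique(c("aap_registry", class(out))))
}

#' Registry hash
#'
#' Deterministic hash over the registry's types, sizes and parameters; stored
#' as provenance on every feature matrix.
#'
#' @param registry An `aap_registry` tibble.
#' @return A character hash.
#' @export
registry_hash <- function(registry) {
  digest::digest(list(registry$type, registry$size, registry$params))
}

#' Write a registry manifest
#'
#' Serializes the registry (type, size, parameters) to a JSON text file so the
#' exact encoding layout travels with derived artifacts.
#'
#' @param registry An `aap_registry` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry_manifest <- function(registry, path) {
  manifest <- list(
    hash = registry_hash(registry),
    n_types = nrow(registry),
    n_values = sum(registry$size),
    specs = purrr::pmap(registry, function(type, size, params) {
      list(type = type, size = size, params = params)
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

encode_one_spec <- function(sequence, type, params) {
  switch(type,
    length  = encode_length(sequence),
    AAC     = encode_aac(sequence),
    DPC     = encode_dpc(sequence),
    GAAC    = encode_gaac(sequence),
    GDPC    = encode_gdpc(sequence),
    CKSAAP  = encode_cksaap(sequence, kmax = params$kmax %||% 2),
    CKSAAGP = encode_cksaagp(sequence, kmax = params$kmax %||% 5),
    APAAC   = encode_apaac(sequence, lambda = params$lambda %||% 5,
                           w = params$w %||% 0.05),
    PAAC    = encode_paac(sequence, lambda = params$lambda %||% 5,
                          w = params$w %||% 0.05),
    SEP     = encode_sep(sequence),
    SER     = encode_ser(sequence),
    DDE     = encode_dde(sequence),
    CTriad  = encode_ctriad(sequence),
    CTDC    = encode_ctdc(sequence),
    CTDT    = encode_ctdt(sequence),
    CTDD    = encode_ctdd(sequence),
    DDR     = encode_ddr(sequence),
    Ez      = encode_scale_descriptor(sequence, "Ez", params$lags),
    Z3      = encode_scale_descriptor(sequence, "Z3", params$lags),
    Z5      = encode_scale_descriptor(sequence, "Z5", params$lags),
    Cougar  = encode_scale_descriptor(sequence, "Cougar", params$lags),
    ABHPRK  = encode_scale_descriptor(sequence, "ABHPRK", params$lags),
    {
      if (startsWith(type, "AAindex.")) {
        encode_aaindex_descriptor(sequence, params$accession,
                                  params$lags %||% 1:10)
      } else {
        stop("no encoder for descriptor type: ", type, call. = FALSE)
      }
    }
  )
}

#' Encode one peptide with a registry
#'
#' @param sequence Peptide sequence string.
#' @param registry An `aap_registry` tibble (default [default_registry()]).
#' @return Named numeric vector; names are `"<TYPE>.<feature>"` and the total
#'   length equals `sum(registry$size)`.
#' @export
encode_peptide <- function(sequence, registry = default_registry()) {
  parts <- purrr::pmap(registry, function(type, size, params) {
    v <- encode_one_spec(sequence, type, params)
    if (length(v) != size) {
      stop("descriptor ", type, " produced ", length(v),
           " values, declared size is ", size, call. = FALSE)
    }
    stats::setNames(v, paste0(type, ".", names(v)))
  })
  unlist(parts)
}

#' Encode a labeled peptide dataset into a feature matrix
#'
#' Applies every descriptor in the registry to every peptide, producing a
#' samples-by-features tibble. Encoding warnings (short-sequence zero fills)
#' are collected and re-emitted once as a summary. Encoding is deterministic
#' and per-sample (row order permutes with the input).
#'
#' @param data Tibble with columns `id`, `sequence` and optionally `label`;
#'   the label column, when present, is carried through.
#' @param registry An `aap_registry` tibble (default [default_registry()]).
#' @return A tibble with columns `sample_id`, (`label`,) then one column per
#'   feature, named `"<TYPE>.<feature>"`. Attributes: `registry_hash`.
#' @export
encode_peptides <- function(data, registry = default_registry()) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  if (anyDuplicated(data$id)) {
    stop("peptide ids must be unique", call. = FALSE)
  }
  warn_tally <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    rows[[i]] <- withCallingHandlers(
      tryCatch(
        encode_peptide(data$sequence[i], registry),
        error = function(e) {
          stop("encoding failed for sample '", data$id[i], "': ",
               conditionMessage(e), call. = FALSE)
        }
      ),
      warning = function(w) {
        msg <- conditionMessage(w)
        cur <- get0(msg, envir = warn_tally, ifnotfound = 0L)
        assign(msg, cur + 1L, envir = warn_tally)
        invokeRestart("muffleWarning")
      }
    )
  }
  msgs <- ls(warn_tally)
  if (length(msgs)) {
    warning("encoding notes: ",
            paste(vapply(msgs, function(m) {
              paste0(m, " (x", get(m, envir = warn_tally), ")")
            }, character(1)), collapse = "; "), call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = data$id), out)
  if ("label" %in% names(data)) {
    out <- dplyr::bind_cols(out[, 1, drop = FALSE],
                            tibble::tibble(label = as.integer(data$label)),
                            out[, -1, drop = FALSE])
  }
  attr(out, "registry_hash") <- registry_hash(registry)
  out
}

#' Feature columns of a feature-matrix tibble
#'
#' @param data A feature-matrix tibble (from [encode_peptides()] or the
#'   synthetic generator).
#' @return Character vector of feature column names (everything except
#'   `sample_id` and `label`).
#' @export
feature_names <- function(data) {
  setdiff(names(data), c("sample_id", "label"))
}

#' Write / read a feature matrix as CSV
#'
#' @param data Feature-matrix tibble.
#' @param path CSV path (header row; `sample_id` first column).
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_feature_matrix <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if ("label" %in% names(out)) out$label <- as.integer(out$label)
  out
}
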