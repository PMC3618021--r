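# Native genotype TSV dialect
# ---------------------------
# line 1 : sample_id <TAB> snp ids...
# line 2 : #chromosome <TAB> chromosome per SNP
# line 3 : #position   <TAB> 1-based position per SNP
# line 4 : #alleles    <TAB> major/minor pair per SNP, e.g. "A/G"
# line 5+: sample id   <TAB> one token per SNP (A_A | A_B | B_B | NoCall)

#' Read a genotype matrix from disk
#'
#' @param path File path.
#' @param format `"native_tsv"` (the package's tab-delimited dialect) or
#'   `"vcf"` (VCF 4.x, read via the vcfR package).
#' @return A [genotype_matrix()].
#'
#' @details For VCF input, genotypes `0/0`, `0/1` (or `1/0`, phased or
#'   not), `1/1` and `./.` map to major homozygote, heterozygote, minor
#'   homozygote and NoCall, with REF taken as the major allele character.
#'   Multi-allelic genotypes and half-calls are coerced to NoCall with a
#'   warning; the method's genotype alphabet is strictly four symbols.
#' @export
read_genotypes <- function(path, format = c("native_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         native_tsv = read_genotypes_tsv(path),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) {
    stop("truncated genotype file (need header + 3 metadata lines): ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "sample_id") {
    stop("line 1: expected first column 'sample_id', got '", header[1L], "'")
  }
  snp_names <- header[-1L]
  n_snp <- length(snp_names)
  if (anyDuplicated(snp_names)) {
    stop("duplicate SNP ids in header: ",
         paste(unique(snp_names[duplicated(snp_names)]), collapse = ", "))
  }
  meta <- list(chromosome = NULL, position = NULL, alleles = NULL)
  for (i in 2:4) {
    row <- fields[[i]]
    key <- sub("^#", "", row[1L])
    if (!startsWith(row[1L], "#") || !key %in% names(meta)) {
      stop("line ", i, ": expected metadata line #chromosome/#position/#alleles, got '",
           row[1L], "'")
    }
    if (length(row) - 1L != n_snp) {
      stop("line ", i, ": expected ", n_snp + 1L, " columns, found ", length(row))
    }
    meta[[key]] <- row[-1L]
  }
  if (any(vapply(meta, is.null, logical(1)))) {
    stop("metadata lines 2-4 must cover #chromosome, #position and #alleles")
  }
  allele_pairs <- strsplit(meta$alleles, "/", fixed = TRUE)
  if (n_snp > 0L && any(lengths(allele_pairs) != 2L)) {
    stop("line 4: allele entries must be 'major/minor' pairs")
  }
  body <- fields[-(1:4)]
  n_sample <- length(body)
  calls <- matrix(NA_integer_, nrow = n_sample, ncol = n_snp)
  ids <- character(n_sample)
  for (j in seq_len(n_sample)) {
    row <- body[[j]]
    line_no <- j + 4L
    if (length(row) != n_snp + 1L) {
      stop("line ", line_no, ": expected ", n_snp + 1L,
           " columns, found ", length(row))
    }
    ids[j] <- row[1L]
    tokens <- row[-1L]
    code <- match(tokens, GENO_TOKENS)
    if (anyNA(code)) {
      bad <- tokens[is.na(code)][1L]
      stop("line ", line_no, ": unknown genotype token '", bad, "'")
    }
    calls[j, ] <- ifelse(code == 4L, NA_integer_, code - 1L)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rownames(calls) <- ids
  colnames(calls) <- snp_names
  info <- data.frame(
    snp_id = snp_names,
    chromosome = meta$chromosome,
    position = suppressWarnings(as.integer(meta$position)),
    allele_major = vapply(allele_pairs, `[`, character(1), 1L),
    allele_minor = vapply(allele_pairs, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  if (n_snp > 0L && anyNA(info$position)) {
    stop("line 3: non-integer position entry")
  }
  genotype_matrix(calls, info)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  snp_id <- fix[, "ID"]
  blank <- is.na(snp_id) | snp_id == "." | snp_id == ""
  snp_id[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  chrom <- fix[, "CHROM"]
  chrom <- sub("^chr", "", chrom)
  chrom[chrom %in% c("M", "Mt")] <- "MT"
  chrom[!chrom %in% VALID_CHROMOSOMES] <- "UNKNOWN"
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  alt1 <- vapply(strsplit(alt, ",", fixed = TRUE),
                 function(x) if (length(x) >= 1L) x[1L] else ".", character(1))
  # strip separators, keep only the called alleles
  core <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  code[core %in% "0/0"] <- 0L
  code[core %in% c("0/1", "1/0")] <- 1L
  code[core %in% "1/1"] <- 2L
  unknown <- !is.na(core) & !core %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (any(unknown) || any(multi)) {
    warning(sum(unknown), " genotype(s) outside the biallelic alphabet ",
            "coerced to NoCall (multi-allelic sites/half-calls)")
    code[unknown] <- NA_integer_
  }
  info <- data.frame(
    snp_id = snp_id,
    chromosome = chrom,
    position = as.integer(fix[, "POS"]),
    allele_major = substr(fix[, "REF"], 1L, 1L),
    allele_minor = substr(alt1, 1L, 1L),
    stringsAsFactors = FALSE
  )
  # REF is treated as the major-allele character; genotype matching at
  # prediction time is by unordered allele pair, so this is a labelling
  # convention, not an assumption about frequencies.
  calls <- t(code)
  colnames(calls) <- info$snp_id
  genotype_matrix(calls, info)
}

#' Write a genotype matrix in the native TSV dialect
#'
#' `read_genotypes()` inverts this exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(gm, path) {
  validate_genotype_matrix(gm)
  info <- gm$snp_info
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("sample_id", info$snp_id), collapse = "\t"), con)
  writeLines(paste(c("#chromosome", info$chromosome), collapse = "\t"), con)
  writeLines(paste(c("#position", info$position), collapse = "\t"), con)
  allele_col <- if (nrow(info) > 0L) {
    paste0(info$allele_major, "/", info$allele_minor)
  } else character(0)
  writeLines(paste(c("#alleles", allele_col), collapse = "\t"), con)
  calls <- gm$calls
  tokens <- matrix(GENO_TOKENS[ifelse(is.na(calls), 4L, calls + 1L)],
                   nrow = nrow(calls))
  for (i in seq_len(nrow(calls))) {
    writeLines(paste(c(rownames(calls)[i], tokens[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

# ---- model serialization ----------------------------------------------

MODEL_FORMAT_VERSION <- "1.0"

serialize_node <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf",
         label = node$label,
         class_counts = as.list(node$class_counts))
  } else {
    list(type = "internal",
         snp_id = node$snp_id,
         left_genotypes = as.integer(node$left_genotypes),
         class_counts = as.list(node$class_counts),
         left = serialize_node(node$left),
         right = serialize_node(node$right))
  }
}

deserialize_node <- function(x) {
  counts <- vapply(x$class_counts, as.numeric, numeric(1))
  if (identical(x$type, "leaf")) {
    leaf_node(label = x$label, class_counts = counts)
  } else if (identical(x$type, "internal")) {
    internal_node(snp_id = x$snp_id,
                  left_genotypes = as.integer(unlist(x$left_genotypes)),
                  class_counts = counts,
                  left = deserialize_node(x$left),
                  right = deserialize_node(x$right))
  } else {
    stop("malformed model file: unknown node type '", x$type, "'")
  }
}

serialize_meta <- function(meta) {
  if (inherits(meta$params, "tree_params")) {
    p <- unclass(meta$params)
    if (is.infinite(p$max_leaves)) p$max_leaves <- "unbounded"
    meta$params <- p
  }
  meta
}

#' Save a trained disjoint-tree ensemble as structured text (JSON)
#'
#' The file is version-tagged; [load_model()] restores the ensemble
#' bit-exactly (class order, node structure, allele pairs, training
#' metadata and seed).
#'
#' @param ensemble A `disjoint_ensemble` from [train_ensemble()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "disjoint_ensemble"))
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    class_order = as.list(ensemble$class_order),
    snp_alleles = lapply(ensemble$snp_alleles, function(p) {
      list(allele_major = p[[1L]], allele_minor = p[[2L]])
    }),
    trees = lapply(ensemble$trees, function(tr) {
      list(snp_set = as.list(tr$snp_set), root = serialize_node(tr$root))
    }),
    meta = serialize_meta(ensemble$meta)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a disjoint-tree ensemble from a model file
#'
#' @param path A model file written by [save_model()].
#' @return A `disjoint_ensemble`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed or truncated model file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(doc$format_version)) stop("model file lacks a format_version field")
  if (!identical(doc$format_version, MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version '", doc$format_version,
         "' (this build reads version ", MODEL_FORMAT_VERSION, ")")
  }
  class_order <- vapply(doc$class_order, as.character, character(1))
  snp_alleles <- lapply(doc$snp_alleles, function(p) {
    c(allele_major = p$allele_major, allele_minor = p$allele_minor)
  })
  trees <- lapply(doc$trees, function(tr) {
    root <- deserialize_node(tr$root)
    new_decision_tree(root = root, class_order = class_order)
  })
  meta <- doc$meta
  if (!is.null(meta$params)) {
    p <- meta$params
    if (identical(p$max_leaves, "unbounded")) p$max_leaves <- Inf
    meta$params <- do.call(tree_params, p)
  }
  if (!is.null(meta$n_trees_requested)) {
    meta$n_trees_requested <- as.integer(meta$n_trees_requested)
  }
  if (!is.null(meta$seed)) meta$seed <- as.integer(meta$seed)
  new_disjoint_ensemble(trees = trees, class_order = class_order,
                        snp_alleles = snp_alleles, meta = meta)
}
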