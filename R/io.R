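# File formats: Oxford GEN-style genotype probability rows, hard-call
# TSVs, result/study TSVs and YAML study configs.  Genotype coding in
# all files: 0/1/2 = copies of alleleB (the coded allele); GEN triples
# are ordered (AA, AB, BB), i.e. by copies of alleleB.

.parse_gen_file <- function(path, rsid = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no SNP rows in ", path, call. = FALSE)
  rows <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(rows, function(x) x[2L], character(1))
  if (length(rows) > 1L) {
    if (is.null(rsid))
      stop(path, " contains ", length(rows), " SNPs; an rsid ",
           "selector is required", call. = FALSE)
    hit <- which(ids == rsid)
    if (!length(hit))
      stop("rsid ", rsid, " not found in ", path, call. = FALSE)
    row <- rows[[hit[1L]]]
  } else {
    row <- rows[[1L]]
    if (!is.null(rsid) && ids[1L] != rsid)
      stop("rsid ", rsid, " not found in ", path, call. = FALSE)
  }
  if (length(row) < 8L || (length(row) - 5L) %% 3L != 0L)
    stop("malformed GEN row in ", path, ": expected 5 + 3n fields, ",
         "got ", length(row), call. = FALSE)
  probs <- suppressWarnings(as.numeric(row[-(1:5)]))
  if (any(is.na(probs)))
    stop("non-numeric probability in ", path, call. = FALSE)
  m <- matrix(probs, ncol = 3L, byrow = TRUE)
  sums <- rowSums(m)
  bad <- which(sums < 0.95 | sums > 1.05)
  if (length(bad))
    stop("individual ", bad[1L], " in ", path, ": probability triple ",
         "sums to ", format(sums[bad[1L]]),
         ", outside [0.95, 1.05]", call. = FALSE)
  list(snp_id = row[1L], rs_id = row[2L],
       position = as.integer(row[3L]),
       alleleA = row[4L], alleleB = row[5L],
       probs = m / sums)
}

#' Read a pair of Oxford GEN-style probability files
#'
#' Each file carries one row per SNP: `snp_id rs_id position alleleA
#' alleleB` followed by three genotype probabilities per individual,
#' ordered by copies of alleleB (0, 1, 2).  Triples whose sum deviates
#' from 1 by more than 0.05 are rejected; the rest are renormalized
#' (GEN files are typically rounded to a few decimals).  Files with
#' several SNP rows need an rsid selector.
#'
#' @param path_G,path_H GEN files for markers G and H.
#' @param sample_path optional Oxford `.sample` file; only its
#'   individual count is checked (2 header lines, then one row per
#'   individual).
#' @param rsid_G,rsid_H rsid selectors for multi-SNP files.
#' @return A [posterior_matrix()] with attributes `snp_G` and `snp_H`
#'   carrying the parsed SNP metadata.
#' @export
read_gen_pair <- function(path_G, path_H, sample_path = NULL,
                          rsid_G = NULL, rsid_H = NULL) {
  g <- .parse_gen_file(path_G, rsid_G)
  h <- .parse_gen_file(path_H, rsid_H)
  if (nrow(g$probs) != nrow(h$probs))
    stop("individual counts differ: ", nrow(g$probs), " in ", path_G,
         " vs ", nrow(h$probs), " in ", path_H, call. = FALSE)
  if (!is.null(sample_path)) {
    ns <- length(readLines(sample_path, warn = FALSE)) - 2L
    if (ns != nrow(g$probs))
      stop("sample file lists ", ns, " individuals but GEN files ",
           "carry ", nrow(g$probs), call. = FALSE)
  }
  post <- posterior_matrix(g$probs, h$probs)
  attr(post, "snp_G") <- g[c("snp_id", "rs_id", "position", "alleleA",
                             "alleleB")]
  attr(post, "snp_H") <- h[c("snp_id", "rs_id", "position", "alleleA",
                             "alleleB")]
  post
}

#' Write one marker's posteriors as an Oxford GEN-style row
#'
#' @param probs n x 3 matrix of genotype probabilities (columns =
#'   0/1/2 copies of alleleB).
#' @param path output file.
#' @param snp_id,rs_id,position,alleleA,alleleB SNP metadata.
#' @param digits decimal places written (default 6).
#' @export
write_gen <- function(probs, path, snp_id = "snp1", rs_id = "rs1",
                      position = 1L, alleleA = "A", alleleB = "B",
                      digits = 6L) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 3L)
    stop("probs must have 3 columns", call. = FALSE)
  vals <- formatC(as.vector(t(probs)), digits = digits,
                  format = "f")
  row <- paste(c(snp_id, rs_id, position, alleleA, alleleB, vals),
               collapse = " ")
  writeLines(row, path)
  invisible(path)
}

#' Read hard genotype calls from a TSV
#'
#' Expects a header `sample G H` and one row per individual with
#' genotype values in `{0, 1, 2}`.
#'
#' @param path TSV file.
#' @return List with `sample` (character), `G` and `H` (integer
#'   vectors), in file order.
#' @export
read_calls_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t",
               colClasses = c("character", "character", "character"),
               check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("sample", "G", "H")
  if (!all(need %in% names(df)))
    stop(path, " must have columns sample, G, H", call. = FALSE)
  if (nrow(df) == 0L) stop("no samples", call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id: ",
         df$sample[anyDuplicated(df$sample)], call. = FALSE)
  for (col in c("G", "H")) {
    bad <- which(!(df[[col]] %in% c("0", "1", "2")))
    if (length(bad))
      stop("non-genotype value \"", df[[col]][bad[1L]],
           "\" in column ", col, " at line ", bad[1L] + 1L,
           call. = FALSE)
  }
  list(sample = df$sample, G = as.integer(df$G), H = as.integer(df$H))
}

#' Write hard calls as a TSV
#' @param G,H genotype vectors.
#' @param path output file.
#' @param sample optional sample ids (default `ind1..indn`).
#' @export
write_calls_tsv <- function(G, H, path, sample = NULL) {
  if (is.null(sample)) sample <- paste0("ind", seq_along(G))
  df <- data.frame(sample = sample, G = G, H = H)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize test results to TSV
#'
#' @param results a single `"epi_test_result"` or a list of them.
#' @param path output file, or `""` for stdout.
#' @export
write_result_tsv <- function(results, path = "") {
  if (inherits(results, "epi_test_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    w <- if (is.null(r$weights)) NA_character_ else
      paste(formatC(r$weights$w, digits = 6, format = "f"),
            collapse = ",")
    data.frame(method = r$method,
               statistic = r$statistic,
               p_value = r$p.value,
               variance = r$provenance,
               reference = r$reference,
               weights = w)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Serialize a study result to TSV
#'
#' One row per method: rejection rate, Monte Carlo standard error,
#' exclusion count and the study parameters.
#'
#' @param result a [run_study()] result.
#' @param path output file, or `""` for stdout.
#' @param pvalues_path optional file for the per-replicate p-values.
#' @export
write_study_tsv <- function(result, path = "", pvalues_path = NULL) {
  cfg <- result$config
  df <- data.frame(method = names(result$rejection),
                   model = cfg$model$kind,
                   n = cfg$n_cases,
                   replicates = cfg$replicates,
                   alpha = result$alpha,
                   rejection_rate = unname(result$rejection),
                   mc_se = unname(result$mc_se),
                   excluded = result$excluded)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pvalues_path))
    write.table(as.data.frame(result$pvalues), pvalues_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the arguments of [study_config()]; `model`,
#' `imputation_G` and `imputation_H` are nested maps passed to
#' [penetrance_model()] and [imputation_config()].  Unknown keys are
#' rejected by name.
#'
#' @param path YAML file.
#' @return A [study_config()].
#' @export
read_study_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- c("model", "maf_G", "maf_H", "imputation_G", "imputation_H",
             "n_cases", "replicates", "alpha_size", "alpha_power",
             "methods", "seed", "mc_draws", "zero_policy",
             "shared_weights")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(y$model) || is.null(y$model$kind))
    stop("config needs a model section with a kind", call. = FALSE)
  mk <- setdiff(names(y$model), c("kind", "f", "g", "mu", "alpha",
                                  "gamma"))
  if (length(mk))
    stop("unknown model keys: ", paste(mk, collapse = ", "),
         call. = FALSE)
  y$model <- do.call(penetrance_model, y$model)
  for (nm in c("imputation_G", "imputation_H")) {
    if (!is.null(y[[nm]])) {
      ik <- setdiff(names(y[[nm]]), c("maf", "tag_maf", "r",
                                      "reference_haplotypes"))
      if (length(ik))
        stop("unknown ", nm, " keys: ", paste(ik, collapse = ", "),
             call. = FALSE)
      y[[nm]] <- do.call(imputation_config, y[[nm]])
    }
  }
  do.call(study_config, y)
}
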