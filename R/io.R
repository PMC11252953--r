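#' Write a dataset as a single ADAT-like tab-delimited file
#'
#' A simplified analogue of aptamer-platform ADAT exports: a metadata header
#' block of `!Key<TAB>value` lines followed by three `^`-marked sections
#' (`^SAMPLES`, `^ANNOTATIONS`, `^MATRIX`), each a tab-delimited table. The
#' matrix section has samples as rows and aptamer sequence IDs as columns.
#'
#' @param dataset list with `intensity`, `samples`, `annotations` (see
#'   [sample_dataset()]).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_adat_like <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("!Scale\t", dataset$intensity$scale),
               paste0("!Aptamers\t", length(dataset$intensity$seq_ids)),
               paste0("!Samples\t", length(dataset$intensity$sample_ids))),
             con)
  tsv <- function(d) {
    writeLines(paste(names(d), collapse = "\t"), con)
    writeLines(do.call(paste, c(lapply(d, as.character), sep = "\t")), con)
  }
  writeLines("^SAMPLES", con)
  tsv(dataset$samples)
  writeLines("^ANNOTATIONS", con)
  tsv(dataset$annotations)
  writeLines("^MATRIX", con)
  m <- dataset$intensity$values
  tsv(data.frame(sample_id = rownames(m), m, check.names = FALSE))
  invisible(path)
}

#' Read an ADAT-like file written by [write_adat_like()]
#'
#' @param path file path.
#' @return list with `intensity`, `samples`, `annotations`.
#' @export
read_adat_like <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^!", lines, value = TRUE)
  meta <- do.call(rbind, strsplit(sub("^!", "", hdr), "\t"))
  scale <- meta[meta[, 1] == "Scale", 2]
  marks <- grep("^\\^", lines)
  names(marks) <- sub("^\\^", "", lines[marks])
  section <- function(name) {
    start <- marks[[name]] + 1
    nxt <- marks[marks > marks[[name]]]
    end <- if (length(nxt)) min(nxt) - 1 else length(lines)
    read.delim(text = paste(lines[start:end], collapse = "\n"),
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  samples <- section("SAMPLES")
  if (!is.null(samples$replicate_of))
    samples$replicate_of <- as.character(samples$replicate_of)
  ann <- section("ANNOTATIONS")
  ann$uniprot_ids[is.na(ann$uniprot_ids)] <- ""
  mt <- section("MATRIX")
  vals <- as.matrix(mt[, -1, drop = FALSE])
  rownames(vals) <- mt[[1]]
  list(intensity = intensity_matrix(vals, scale = scale),
       samples = samples, annotations = ann)
}
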