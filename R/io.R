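## Exchange-directory layout shared by the MTX writer and the h5ad bridge:
##   X.mtx              counts, genes x cells (MatrixMarket, integer)
##   var.tsv            gene_id column
##   obs.tsv            cell_id column, plus cell_type when labels exist
##   layer_<assay>.mtx    one per additional assay (mask, mu, denoised...)

write_exchange_dir <- function(sce, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    counts <- assay(sce, "counts")
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
        "generalMatrix"), file.path(dir, "X.mtx"))
    write.table(data.frame(gene_id = rownames(sce)),
        file.path(dir, "var.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    obs <- data.frame(cell_id = colnames(sce))
    if ("cell_type" %in% colnames(colData(sce))) {
        obs$cell_type <- as.character(colData(sce)$cell_type)
    }
    write.table(obs, file.path(dir, "obs.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    for (layer in setdiff(assayNames(sce), "counts")) {
        m <- assay(sce, layer)
        storage.mode(m) <- "double"
        Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
            "generalMatrix"),
            file.path(dir, sprintf("layer_%s.mtx", layer)))
    }
    invisible(dir)
}

read_exchange_dir <- function(dir) {
    xPath <- file.path(dir, "X.mtx")
    if (!file.exists(xPath)) stop("malformed exchange data: missing X.mtx")
    counts <- as.matrix(Matrix::readMM(xPath))
    var <- read.delim(file.path(dir, "var.tsv"), stringsAsFactors = FALSE)
    if (!"gene_id" %in% colnames(var)) {
        stop("malformed exchange data: var.tsv lacks a 'gene_id' column")
    }
    obs <- read.delim(file.path(dir, "obs.tsv"), stringsAsFactors = FALSE)
    if (!"cell_id" %in% colnames(obs)) {
        stop("malformed exchange data: obs.tsv lacks a 'cell_id' column")
    }
    if (nrow(var) != nrow(counts) || nrow(obs) != ncol(counts)) {
        stop("malformed exchange data: matrix dimensions (", nrow(counts),
            " x ", ncol(counts), ") disagree with var/obs tables")
    }
    if (max(abs(counts - round(counts))) == 0) {
        storage.mode(counts) <- "integer"
    }
    dimnames(counts) <- list(var$gene_id, obs$cell_id)
    assays <- list(counts = counts)
    layerFiles <- list.files(dir, pattern = "^layer_.*\\.mtx$")
    for (f in layerFiles) {
        layer <- sub("^layer_(.*)\\.mtx$", "\\1", f)
        m <- as.matrix(Matrix::readMM(file.path(dir, f)))
        dimnames(m) <- dimnames(counts)
        if (layer == "dropout_mask") m <- m != 0
        assays[[layer]] <- m
    }
    cd <- if ("cell_type" %in% colnames(obs)) {
        S4Vectors::DataFrame(cell_type = factor(obs$cell_type),
            row.names = obs$cell_id)
    } else {
        S4Vectors::DataFrame(row.names = obs$cell_id)
    }
    SingleCellExperiment(assays = assays, colData = cd)
}

#' Write / read a count matrix as MatrixMarket + TSV
#'
#' Plain-text interchange: `X.mtx` (genes x cells counts), `var.tsv`
#' (gene ids), `obs.tsv` (cell ids and, when present, `cell_type`
#' labels), plus one `layer_<assay>.mtx` per additional assay.
#' The round trip is lossless for counts, identifiers, labels and mask.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param dir directory to write to / read from.
#' @return `readCountsMtx` returns a `SingleCellExperiment`.
#' @export
writeCountsMtx <- function(sce, dir) {
    stopifnot(is(sce, "SummarizedExperiment"))
    write_exchange_dir(sce, dir)
}

#' @rdname writeCountsMtx
#' @export
readCountsMtx <- function(dir) {
    read_exchange_dir(dir)
}

#' Write a count matrix as CSV
#'
#' Genes x cells dense CSV with gene ids in the first column; labels, when
#' present, go to a companion `<path>.labels.csv`.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param path CSV file path.
#' @return `readCountsCsv` returns a `SingleCellExperiment`.
#' @export
writeCountsCsv <- function(sce, path) {
    counts <- assay(sce, "counts")
    df <- data.frame(gene_id = rownames(counts), counts,
        check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    if ("cell_type" %in% colnames(colData(sce))) {
        utils::write.csv(
            data.frame(cell_id = colnames(counts),
                cell_type = as.character(colData(sce)$cell_type)),
            paste0(path, ".labels.csv"), row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}

#' @rdname writeCountsCsv
#' @export
readCountsCsv <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1L]]
    if (max(abs(counts - round(counts))) == 0) {
        storage.mode(counts) <- "integer"
    }
    labPath <- paste0(path, ".labels.csv")
    cd <- if (file.exists(labPath)) {
        lab <- utils::read.csv(labPath)
        S4Vectors::DataFrame(cell_type = factor(lab$cell_type),
            row.names = lab$cell_id)
    } else {
        S4Vectors::DataFrame(row.names = colnames(counts))
    }
    SingleCellExperiment(assays = list(counts = counts), colData = cd)
}

find_python <- function() {
    py <- getOption("dbaae.python", Sys.which("python"))
    if (!nzchar(py)) {
        stop("no 'python' interpreter found on PATH; h5ad I/O bridges to ",
            "the Python 'anndata' library (set options(dbaae.python=) to ",
            "point at an interpreter that has it)")
    }
    py
}

run_bridge <- function(args) {
    script <- system.file("python", "h5ad_bridge.py", package = "dbaae",
        mustWork = TRUE)
    out <- suppressWarnings(system2(find_python(), c(script, args),
        stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L) {
        stop("h5ad bridge failed: ", paste(out, collapse = "\n"))
    }
    invisible(out)
}

#' Write / read AnnData h5ad files
#'
#' Bridges to the Python `anndata` library (which must be importable by
#' the `python` on the PATH, or by the interpreter named in
#' `options(dbaae.python=)`): the matrix travels through a temporary
#' plain-text exchange directory in both directions. On disk, counts are
#' stored cells x genes in `X`, labels in `obs["cell_type"]`, and every
#' additional assay (dropout mask, expected values, denoised layers) as a
#' like-named layer. The round trip is lossless for counts (integer dtype included),
#' identifiers, labels and mask; files without a `cell_type` column read
#' back with labels absent.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param path h5ad file path.
#' @return `readH5ad` returns a `SingleCellExperiment`.
#' @export
writeH5ad <- function(sce, path) {
    stopifnot(is(sce, "SummarizedExperiment"))
    tmp <- tempfile("h5ad_pack_")
    on.exit(unlink(tmp, recursive = TRUE))
    write_exchange_dir(sce, tmp)
    run_bridge(c("pack", "--dir", tmp, "--out", path.expand(path)))
    invisible(path)
}

#' @rdname writeH5ad
#' @export
readH5ad <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    tmp <- tempfile("h5ad_unpack_")
    on.exit(unlink(tmp, recursive = TRUE))
    run_bridge(c("unpack", "--in", path.expand(path), "--dir", tmp))
    read_exchange_dir(tmp)
}
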