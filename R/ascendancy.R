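#' Flow-network container
#'
#' A nonnegative inter-compartment flow matrix: `F[i, j]` is the flow from
#' compartment i to compartment j, in any single consistent unit.
#'
#' @param flows square nonnegative numeric matrix with positive total.
#' @param labels compartment names (defaults to matrix dimnames or C1..Cn).
#' @return an object of class `flow_network` with fields `labels`, `flows`.
#' @export
flow_network <- function(flows, labels = NULL) {
  flows <- as.matrix(flows)
  storage.mode(flows) <- "double"
  if (nrow(flows) != ncol(flows)) stop("flow matrix must be square")
  if (anyNA(flows) || any(flows < 0)) stop("flows must be finite and nonnegative")
  if (sum(flows) <= 0) stop("total flow must be positive")
  n <- nrow(flows)
  if (is.null(labels)) labels <- rownames(flows)
  if (is.null(labels)) labels <- paste0("C", seq_len(n))
  if (length(labels) != n) stop("need one label per compartment")
  dimnames(flows) <- list(labels, labels)
  structure(list(labels = labels, flows = flows), class = "flow_network")
}

#' Read a flow network from file
#'
#' Two dialects: a square CSV whose header row and first column carry the
#' compartment labels, or a TSV edge list `source<TAB>target<TAB>flow`
#' (missing edges are zero flows).
#'
#' @param path input file.
#' @param format `"auto"` (TSV extension or 3 unnamed-looking columns means
#'   edge list), `"matrix"` or `"edgelist"`.
#' @return a [flow_network].
#' @export
read_flow_network <- function(path, format = c("auto", "matrix", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "edgelist" else "matrix"
  if (format == "matrix") {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
    flow_network(as.matrix(df), labels = rownames(df))
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("source", "target", "flow"))
    labels <- sort(unique(c(df$source, df$target)))
    f <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (r in seq_len(nrow(df)))
      f[df$source[r], df$target[r]] <- f[df$source[r], df$target[r]] + df$flow[r]
    flow_network(f, labels)
  }
}

#' Joint and marginal flow probabilities
#'
#' Normalizes the flow matrix by the total system throughput:
#' p(a_i, b_j) = F_ij / sum(F), with source marginals p(a_i) (row sums) and
#' target marginals p(b_j) (column sums).
#'
#' @param net a [flow_network].
#' @return list with `joint` (matrix), `p_source`, `p_target`.
#' @export
flow_probabilities <- function(net) {
  joint <- net$flows / sum(net$flows)
  list(joint = joint, p_source = rowSums(joint), p_target = colSums(joint))
}

#' Ascendancy as average mutual information of a flow network
#'
#' As = K * sum_ij p(a_i, b_j) log2[ p(b_j | a_i) / p(b_j) ], the average
#' mutual information (in bits for K = 1) between where flow comes from and
#' where it goes.  Capacity is the joint flow entropy -K * sum p log2 p, the
#' upper bound on ascendancy; overhead = capacity - ascendancy is the
#' redundancy of parallel pathways, associated with resilience.  Terms with
#' zero joint probability contribute zero.
#'
#' @param net a [flow_network].
#' @param K positive scaling constant (default 1: pure information units).
#' @param scale `"none"` (K as given) or `"throughput"` (K multiplied by the
#'   total system throughput, Ulanowicz's dimensional ascendancy).
#' @return an object of class `ascendancy_report`: list with `ami`,
#'   `capacity`, `overhead`, `K`.
#' @export
ascendancy_ami <- function(net, K = 1, scale = c("none", "throughput")) {
  scale <- match.arg(scale)
  if (K <= 0) stop("K must be positive")
  if (scale == "throughput") K <- K * sum(net$flows)
  pr <- flow_probabilities(net)
  jp <- pr$joint
  pos <- jp > 0
  denom <- outer(pr$p_source, pr$p_target)
  ami <- sum(jp[pos] * log2(jp[pos] / denom[pos]))
  capacity <- -sum(jp[pos] * log2(jp[pos]))
  structure(list(ami = K * ami, capacity = K * capacity,
                 overhead = K * (capacity - ami), K = K),
            class = "ascendancy_report")
}

#' @export
print.ascendancy_report <- function(x, ...) {
  cat(sprintf("<ascendancy_report> AMI = %.4g, capacity = %.4g, overhead = %.4g (K = %g)\n",
              x$ami, x$capacity, x$overhead, x$K))
  invisible(x)
}
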