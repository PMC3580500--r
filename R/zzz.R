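#' @importFrom stats loess loess.control predict sd median quantile dnorm
#'   qnorm pnorm rlnorm rpois runif rbinom setNames wilcox.test cor.test
#'   chisq.test
#' @importFrom utils combn head tail
NULL

.datatable.aware <- TRUE
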