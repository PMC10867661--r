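#include <Rcpp.h>
using namespace Rcpp;

// In-place RMSprop update over a list of dense layers.
//
// `layers`, `grads` and `state` are parallel lists of list(W, b); W and b
// of `layers`/`state` are modified in place (the R callers deep-copy the
// model once per training run before using this path, so no other binding
// can observe the mutation). Update rule per parameter:
//   v <- rho * v + (1 - rho) * g^2
//   w <- w - lr * g / (sqrt(v) + eps)
static void update_one(NumericVector w, NumericVector g, NumericVector v,
                       double lr, double rho, double eps) {
    const R_xlen_t n = w.size();
    for (R_xlen_t i = 0; i < n; ++i) {
        const double gi = g[i];
        const double vi = rho * v[i] + (1.0 - rho) * gi * gi;
        v[i] = vi;
        w[i] -= lr * gi / (std::sqrt(vi) + eps);
    }
}

// [[Rcpp::export(name = ".rmsprop_step_inplace")]]
void rmsprop_step_inplace(List layers, List grads, List state, double lr,
                          double rho, double eps) {
    const R_xlen_t nl = layers.size();
    for (R_xlen_t l = 0; l < nl; ++l) {
        List layer = layers[l];
        List grad = grads[l];
        List st = state[l];
        update_one(layer["W"], grad["W"], st["W"], lr, rho, eps);
        update_one(layer["b"], grad["b"], st["b"], lr, rho, eps);
    }
}
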