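// Felsenstein pruning for reversible substitution models over an arbitrary
// state space (61 sense codons here; the code is agnostic to the dimension).
// Site-class mixtures (branch-site models) are handled by letting every edge
// carry a possibly different rate-matrix category per site class; classes
// that differ only on a few (foreground) edges share the per-edge partial
// contributions of the unaffected subtrees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build P(t) = U diag(exp(lambda t)) Uinv from a cached eigendecomposition.
static arma::mat trans_prob(const arma::vec& values, const arma::mat& U,
                            const arma::mat& Uinv, double t) {
    arma::mat P = U * arma::diagmat(arma::exp(values * t)) * Uinv;
    // clamp tiny negative round-off so partial likelihoods stay non-negative
    P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    return P;
}

// Per-pattern log-likelihood under each site class.
//
// states:  ntip x npat integer matrix, 0-based state index, -1 = missing
// edge:    n_edge x 2, 1-based ape node ids, postorder (children first)
// el:      n_edge x n_cat effective edge lengths (a category with a
//          relative rate r uses el * r, precomputed by the caller)
// eig:     list of categories, each list(values, U, Uinv)
// catmap:  n_edge x n_class, 0-based index into eig
// pi:      root frequencies (length = state count)
//
// Returns npat x n_class matrix of log-likelihoods.
// [[Rcpp::export(name = ".pruning_loglik_cpp")]]
NumericMatrix pruning_loglik_cpp(IntegerMatrix states, IntegerMatrix edge,
                                 NumericMatrix el, int ntip, List eig,
                                 IntegerMatrix catmap, NumericVector pi) {
    const int npat = states.ncol();
    const int n_edge = edge.nrow();
    const int n_class = catmap.ncol();
    const int ns = pi.size();
    const int n_nodes = ntip + n_edge + 2;  // upper bound on node ids

    const int n_cat = eig.size();
    std::vector<arma::vec> ev(n_cat);
    std::vector<arma::mat> eU(n_cat), eV(n_cat);
    for (int k = 0; k < n_cat; ++k) {
        List e = eig[k];
        ev[k] = as<arma::vec>(e["values"]);
        eU[k] = as<arma::mat>(e["U"]);
        eV[k] = as<arma::mat>(e["Uinv"]);
    }
    arma::vec piv = as<arma::vec>(pi);

    // transition matrices cached per (edge, category)
    std::vector<std::vector<arma::mat>> Pcache(n_edge,
        std::vector<arma::mat>(n_cat));
    std::vector<std::vector<char>> Phave(n_edge, std::vector<char>(n_cat, 0));

    // per-edge contributions kept per class so later classes can reuse them
    std::vector<std::vector<arma::mat>> contrib(n_class,
        std::vector<arma::mat>(n_edge));
    // per-class, per-node log-scaling accumulated within each subtree
    std::vector<std::vector<arma::rowvec>> subscale(n_class,
        std::vector<arma::rowvec>(n_nodes,
                                  arma::rowvec(npat, arma::fill::zeros)));

    // subtree_ok[cls][node]: all edges below `node` have the same category
    // under class `cls` as under its base class
    NumericMatrix out(npat, n_class);
    const int root = edge(n_edge - 1, 0);

    for (int cls = 0; cls < n_class; ++cls) {
        // choose the earlier class sharing the most internal-edge work
        int base = -1, best = 0;
        std::vector<char> sub_ok(n_nodes, 0);
        for (int b = 0; b < cls; ++b) {
            std::vector<char> ok(n_nodes, 1);
            int gain = 0;
            for (int e = 0; e < n_edge; ++e) {
                int par = edge(e, 0), chi = edge(e, 1);
                bool eq = catmap(e, cls) == catmap(e, b);
                bool reuse = eq && (chi <= ntip || ok[chi]);
                if (!reuse) ok[par] = 0;
                if (reuse && chi > ntip) ++gain;
            }
            if (gain > best) { best = gain; base = b; sub_ok = ok; }
        }

        std::vector<arma::mat> partial(n_nodes);
        std::vector<char> init(n_nodes, 0);

        for (int e = 0; e < n_edge; ++e) {
            int par = edge(e, 0), chi = edge(e, 1);
            int cat = catmap(e, cls);
            bool reuse = base >= 0 && catmap(e, cls) == catmap(e, base) &&
                         (chi <= ntip || sub_ok[chi]);
            // log-scaling accumulated inside the child's subtree; a reused
            // contribution carries the base class's scaling of that subtree
            if (chi > ntip)
                subscale[cls][par] += subscale[reuse ? base : cls][chi];
            if (reuse) {
                contrib[cls][e] = contrib[base][e];
            } else {
                if (!Phave[e][cat]) {
                    Pcache[e][cat] = trans_prob(ev[cat], eU[cat], eV[cat],
                                                el(e, cat));
                    Phave[e][cat] = 1;
                }
                const arma::mat& P = Pcache[e][cat];
                arma::mat C(ns, npat);
                if (chi <= ntip) {
                    for (int h = 0; h < npat; ++h) {
                        int s = states(chi - 1, h);
                        if (s < 0)
                            C.col(h).ones();
                        else
                            C.col(h) = P.col(s);
                    }
                } else {
                    C = P * partial[chi];
                }
                contrib[cls][e] = std::move(C);
            }
            if (!init[par]) {
                partial[par] = contrib[cls][e];
                init[par] = 1;
            } else {
                partial[par] %= contrib[cls][e];
            }
            // guard against underflow on deep trees: rescale the finished
            // parent partial and book the log factor against its subtree
            if (e == n_edge - 1 || edge(e + 1, 0) != par) {
                arma::rowvec m = arma::max(partial[par], 0);
                bool low = false;
                for (int h = 0; h < npat; ++h)
                    if (m[h] > 0 && m[h] < 1e-120) { low = true; break; }
                if (low) {
                    for (int h = 0; h < npat; ++h) {
                        if (m[h] > 0 && m[h] < 1e-120) {
                            partial[par].col(h) /= m[h];
                            subscale[cls][par][h] += std::log(m[h]);
                        }
                    }
                }
            }
        }
        arma::rowvec lik = piv.t() * partial[root];
        for (int h = 0; h < npat; ++h)
            out(h, cls) = std::log(lik[h]) + subscale[cls][root][h];
    }
    return out;
}
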