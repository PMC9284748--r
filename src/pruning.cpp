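// Felsenstein pruning over a 61-state codon alphabet.
// Partial likelihoods are column-rescaled per edge to avoid underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// tipstate: ntip x npat integer matrix, 0-based codon states, -1 = missing.
// edge: nedge x 2 (parent, child), 0-based node indices, postorder
//       (children appear as child before they appear as parent).
// eigA/eigAinv/eigval: per branch-class eigendecomposition of Q.
// Returns per-pattern log-likelihood at the root under frequencies pi.
// [[Rcpp::export]]
arma::vec cpp_pattern_loglik(const arma::imat& tipstate,
                             const arma::imat& edge,
                             const arma::vec& tlen,
                             const arma::ivec& eclass,
                             const Rcpp::List& eigA,
                             const Rcpp::List& eigAinv,
                             const Rcpp::List& eigval,
                             const arma::vec& pi,
                             const int nnode,
                             const int root)
{
    const int ns = pi.n_elem;
    const int ntip = tipstate.n_rows;
    const int npat = tipstate.n_cols;
    const int nedge = edge.n_rows;

    // transition matrix per edge
    std::vector<mat> P(nedge);
    for (int e = 0; e < nedge; ++e) {
        const mat& A = Rcpp::as<mat>(eigA[eclass[e]]);
        const mat& Ai = Rcpp::as<mat>(eigAinv[eclass[e]]);
        const vec& lam = Rcpp::as<vec>(eigval[eclass[e]]);
        mat Pe = A * (exp(lam * tlen[e]) % Ai.each_col());
        Pe.clamp(0.0, datum::inf);
        P[e] = Pe;
    }

    std::vector<mat> part(nnode);
    std::vector<bool> seen(nnode, false);
    vec logscale(npat, fill::zeros);

    for (int e = 0; e < nedge; ++e) {
        const int par = edge(e, 0);
        const int child = edge(e, 1);
        mat contrib(ns, npat);
        if (child < ntip) {
            // tip: P %*% indicator(state), i.e. a column of P
            for (int s = 0; s < npat; ++s) {
                const int st = tipstate(child, s);
                if (st < 0) contrib.col(s) = sum(P[e], 1);  // missing data
                else        contrib.col(s) = P[e].col(st);
            }
        } else {
            contrib = P[e] * part[child];
        }
        if (!seen[par]) {
            part[par] = contrib;
            seen[par] = true;
        } else {
            part[par] %= contrib;
        }
        // rescale the parent's partial once per incoming edge
        rowvec m = max(part[par], 0);
        for (int s = 0; s < npat; ++s) {
            if (m[s] > 0 && m[s] < 1e-80) {
                part[par].col(s) /= m[s];
                logscale[s] += std::log(m[s]);
            }
        }
    }

    vec lik = part[root].t() * pi;
    vec out(npat);
    for (int s = 0; s < npat; ++s) {
        out[s] = (lik[s] > 0) ? std::log(lik[s]) + logscale[s]
                              : -datum::inf;
    }
    return out;
}
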