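#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-state
// recurrence).  A gap of length L scores gap_open + L * gap_extend, both
// penalties being non-positive on the score scale (BLAST convention, so
// gap_open = -11, gap_extend = -1 reproduces BLASTP's default cost of
// 11 + L for a length-L gap).
//
// Traceback is deterministic: within the H state ties are broken
// diagonal > up (gap in b) > left (gap in a); within the gap states an
// extension is preferred over a fresh opening.  The best cell is the first
// strictly-maximal H value in row-major scan order, so equal-scoring
// alignments resolve to the one ending earliest in a, then in b.

// traceback flags packed per cell
static const unsigned char H_DIAG = 1;  // H came from diagonal
static const unsigned char H_UP   = 2;  // H came from E (gap in b)
static const unsigned char H_LEFT = 3;  // H came from F (gap in a)
static const unsigned char H_MASK = 3;
static const unsigned char E_EXT  = 4;  // E extended an existing gap
static const unsigned char F_EXT  = 8;  // F extended an existing gap

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a_idx, IntegerVector b_idx,
                  IntegerMatrix score_mat,
                  double gap_open, double gap_extend,
                  bool traceback = true) {
    const int n = a_idx.size();
    const int m = b_idx.size();
    const double NEG = -1e18;
    const double go = gap_open + gap_extend;  // cost of opening a length-1 gap

    std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
    std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
    double best = 0.0;
    int best_i = 0, best_j = 0;

    std::vector<unsigned char> tb;
    if (traceback) tb.assign((size_t)(n + 1) * (m + 1), 0);

    const int nrow = score_mat.nrow();
    const int* smat = score_mat.begin();
    std::vector<int> brow(m);
    for (int j = 0; j < m; ++j) brow[j] = b_idx[j] * nrow;

    for (int i = 1; i <= n; ++i) {
        double F = NEG;
        Hcur[0] = 0.0;
        Ecur[0] = NEG;
        const int* srow = smat + a_idx[i - 1];
        double* hp = Hprev.data();
        double* hc = Hcur.data();
        double* ep = Eprev.data();
        double* ec = Ecur.data();
        unsigned char* tbrow =
            traceback ? tb.data() + (size_t)i * (m + 1) : NULL;
        for (int j = 1; j <= m; ++j) {
            unsigned char flag = 0;
            // E: gap in b (vertical move, consumes a_i)
            double e_open = hp[j] + go;
            double e_ext  = ep[j] + gap_extend;
            double E;
            if (e_ext > e_open) { E = e_ext; flag |= E_EXT; }
            else E = e_open;
            // F: gap in a (horizontal move, consumes b_j)
            double f_open = hc[j - 1] + go;
            double f_ext  = F + gap_extend;
            if (f_ext > f_open) { F = f_ext; flag |= F_EXT; }
            else F = f_open;
            // H
            double diag = hp[j - 1] + srow[brow[j - 1]];
            double h = 0.0;
            unsigned char from = 0;
            if (diag >= h && diag > 0) { h = diag; from = H_DIAG; }
            if (E > h) { h = E; from = H_UP; }
            if (F > h) { h = F; from = H_LEFT; }
            hc[j] = h;
            ec[j] = E;
            if (tbrow) tbrow[j] = flag | from;
            if (h > best) { best = h; best_i = i; best_j = j; }
        }
        std::swap(Hprev, Hcur);
        std::swap(Eprev, Ecur);
    }

    if (!traceback || best <= 0.0) {
        return List::create(
            _["score"] = best,
            _["start_a"] = NA_INTEGER, _["end_a"] = NA_INTEGER,
            _["start_b"] = NA_INTEGER, _["end_b"] = NA_INTEGER,
            _["n_columns"] = 0, _["n_identical"] = 0,
            _["a_gapped"] = IntegerVector(0),
            _["b_gapped"] = IntegerVector(0));
    }

    // Traceback from (best_i, best_j).  We stored only direction flags, so
    // walk states backwards; flags are sufficient because the gap-state
    // choice (extend vs open) was recorded per cell.
    std::vector<int> acol, bcol;  // 1-based positions, 0 = gap
    int i = best_i, j = best_j;
    int state = 0;  // 0 = H, 1 = E (up), 2 = F (left)
    int n_ident = 0;
    while (i > 0 || j > 0) {
        unsigned char f = tb[(size_t)i * (m + 1) + j];
        if (state == 0) {
            unsigned char from = f & H_MASK;
            if (from == 0) break;  // local alignment start (H = 0)
            if (from == H_DIAG) {
                acol.push_back(i); bcol.push_back(j);
                if (a_idx[i - 1] == b_idx[j - 1]) ++n_ident;
                --i; --j;
            } else if (from == H_UP) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {
            acol.push_back(i); bcol.push_back(0);
            bool ext = (f & E_EXT) != 0;
            --i;
            if (!ext) state = 0;
        } else {
            acol.push_back(0); bcol.push_back(j);
            bool ext = (f & F_EXT) != 0;
            --j;
            if (!ext) state = 0;
        }
    }
    std::reverse(acol.begin(), acol.end());
    std::reverse(bcol.begin(), bcol.end());
    int ncol = (int)acol.size();
    int start_a = i + 1, start_b = j + 1;

    return List::create(
        _["score"] = best,
        _["start_a"] = start_a, _["end_a"] = best_i,
        _["start_b"] = start_b, _["end_b"] = best_j,
        _["n_columns"] = ncol, _["n_identical"] = n_ident,
        _["a_gapped"] = IntegerVector(acol.begin(), acol.end()),
        _["b_gapped"] = IntegerVector(bcol.begin(), bcol.end()));
}
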