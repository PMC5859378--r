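#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Trio Mendelian incompatibility scan over all candidate sire x dam pairs.
//
// Genotypes are allele dosages 0/1/2 with 3 = missing, loci-major matrices
// (loci x individuals). A locus counts as comparable iff all three genotypes
// are non-missing, and as a mismatch iff additionally the offspring dosage is
// impossible given the parental pair: an offspring receives one gamete from
// each parent, where dosage 0 -> gamete {0}, 1 -> {0,1}, 2 -> {1}.

static inline bool incompatible(int s, int d, int o) {
    if (o == 0) return s == 2 || d == 2;
    if (o == 2) return s == 0 || d == 0;
    /* o == 1 */ return (s == 0 && d == 0) || (s == 2 && d == 2);
}

// [[Rcpp::export(name = ".trio_scan")]]
List trio_scan(IntegerMatrix off_t, IntegerMatrix sire_t, IntegerMatrix dam_t) {
    const int m = off_t.nrow();
    if (sire_t.nrow() != m || dam_t.nrow() != m)
        stop("genotype matrices must share the locus index");
    const int no = off_t.ncol(), ns = sire_t.ncol(), nd = dam_t.ncol();
    if (ns == 0 || nd == 0) stop("empty candidate parent set");

    // lookup over combined codes: pair code pc = s*4 + d (0..15), then
    // idx = pc*4 + o; one table for mismatches, one for comparable loci
    unsigned char tab_mm[64], tab_cmp[64];
    for (int s = 0; s < 4; ++s)
        for (int d = 0; d < 4; ++d)
            for (int o = 0; o < 4; ++o) {
                int idx = (s * 4 + d) * 4 + o;
                bool ok = s < 3 && d < 3 && o < 3;
                tab_cmp[idx] = ok ? 1 : 0;
                tab_mm[idx] = (ok && incompatible(s, d, o)) ? 1 : 0;
            }

    const int npair = ns * nd;
    IntegerMatrix mm(no, npair), cmp(no, npair);
    std::vector<unsigned char> pc(m);
    for (int s = 0; s < ns; ++s) {
        const int *sg = &sire_t(0, s);
        for (int d = 0; d < nd; ++d) {
            const int *dg = &dam_t(0, d);
            const int p = s * nd + d;
            for (int l = 0; l < m; ++l)
                pc[l] = (unsigned char)((sg[l] * 4 + dg[l]) * 4);
            for (int i = 0; i < no; ++i) {
                const int *og = &off_t(0, i);
                int nmm = 0, ncmp = 0;
                for (int l = 0; l < m; ++l) {
                    const int idx = pc[l] + og[l];
                    nmm += tab_mm[idx];
                    ncmp += tab_cmp[idx];
                }
                mm(i, p) = nmm;
                cmp(i, p) = ncmp;
            }
        }
    }
    return List::create(_["mismatch"] = mm, _["compared"] = cmp);
}
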