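// Pigeonhole seed-and-verify search for all genomic occurrences of each
// protospacer within a Hamming-distance budget, with exact (IUPAC) PAM
// verification at every locus.
//
// The protospacer is split into (maxMM + 1) disjoint pieces; any hit with
// <= maxMM substitutions must carry at least one exact piece, so candidate
// loci are gathered from a k-mer index of the genome keyed on the first
// seedW bases of each piece and then verified by direct comparison.
// Sites overlapping an N are rejected outright (unknown sequence).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;   // N or anything else
    }
}

// bitmask of concrete bases allowed by an IUPAC code (A=1,C=2,G=4,T=8)
static inline int iupacMask(char c) {
    switch (c) {
    case 'A': return 1;  case 'C': return 2;
    case 'G': return 4;  case 'T': return 8;
    case 'R': return 5;  case 'Y': return 10;
    case 'S': return 6;  case 'W': return 9;
    case 'K': return 12; case 'M': return 3;
    case 'B': return 14; case 'D': return 13;
    case 'H': return 11; case 'V': return 7;
    case 'N': return 15;
    default:  return 0;
    }
}

static inline char compBase(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    default:  return 'N';
    }
}

typedef std::unordered_map<uint64_t, std::vector<int> > SeedIndex;

struct Chrom {
    std::vector<uint8_t> code;   // 0..3 bases, 4 = N
    std::vector<uint8_t> pamF;   // site start s: PAM ok, plus strand
    std::vector<uint8_t> pamR;   // site start s: PAM ok, minus strand
    SeedIndex index;             // seedW-mer -> genome positions
    int n;
};

// [[Rcpp::export(name = ".pigeonholeMap")]]
List pigeonholeMap(CharacterVector chromSeqs, CharacterVector protospacers,
                   std::string pamPattern, bool pamThreePrime,
                   int maxMM, int hitCap) {
    const int nChrom = chromSeqs.size();
    const int nGuide = protospacers.size();
    const int q = (int) pamPattern.size();
    int P = 0;
    if (nGuide > 0) P = LENGTH(STRING_ELT(protospacers, 0));
    const int L = P + q;
    const int nPiece = maxMM + 1;
    const int seedW = std::max(1, P / nPiece);

    // PAM masks, forward pattern and reverse complement pattern
    std::vector<int> pamMaskF(q), pamMaskR(q);
    for (int j = 0; j < q; ++j) {
        pamMaskF[j] = iupacMask(pamPattern[j]);
        pamMaskR[j] = iupacMask(compBase(pamPattern[q - 1 - j]));
    }
    // offsets of the PAM / protospacer regions inside the L-base footprint
    const int pamOffF = pamThreePrime ? P : 0;
    const int pamOffR = pamThreePrime ? 0 : P;
    const int spOffF  = pamThreePrime ? 0 : q;
    const int spOffR  = pamThreePrime ? q : 0;

    std::vector<Chrom> chroms(nChrom);
    for (int c = 0; c < nChrom; ++c) {
        const char *s = CHAR(STRING_ELT(chromSeqs, c));
        int n = (int) LENGTH(STRING_ELT(chromSeqs, c));
        Chrom &ch = chroms[c];
        ch.n = n;
        ch.code.resize(n);
        for (int i = 0; i < n; ++i) ch.code[i] = (uint8_t) baseCode(s[i]);

        int nSites = n - L + 1;
        if (nSites < 0) nSites = 0;
        ch.pamF.assign(nSites, 0);
        ch.pamR.assign(nSites, 0);
        for (int st = 0; st < nSites; ++st) {
            bool okF = true, okR = true;
            for (int j = 0; j < q && (okF || okR); ++j) {
                uint8_t bF = ch.code[st + pamOffF + j];
                uint8_t bR = ch.code[st + pamOffR + j];
                if (bF > 3 || !((pamMaskF[j] >> bF) & 1)) okF = false;
                if (bR > 3 || !((pamMaskR[j] >> bR) & 1)) okR = false;
            }
            ch.pamF[st] = okF;
            ch.pamR[st] = okR;
        }

        // seed index over clean (N-free) seedW-mers
        if (n >= seedW) {
            uint64_t key = 0;
            const uint64_t mask = (seedW >= 32) ? ~0ULL
                : ((1ULL << (2 * seedW)) - 1);
            int clean = 0;   // length of N-free suffix ending at i
            for (int i = 0; i < n; ++i) {
                uint8_t b = ch.code[i];
                if (b > 3) { clean = 0; key = 0; continue; }
                key = ((key << 2) | b) & mask;
                if (++clean >= seedW)
                    ch.index[key].push_back(i - seedW + 1);
            }
        }
    }

    std::vector<int> outGuide, outChrom, outStart, outMM;
    std::vector<int> outStrand;           // 0 = plus, 1 = minus
    LogicalVector saturated(nGuide);

    std::vector<int> spacer(P), spacerRC(P);
    std::vector<std::pair<int,int> > cand;  // (site start, strand)

    for (int g = 0; g < nGuide; ++g) {
        const char *gs = CHAR(STRING_ELT(protospacers, g));
        if ((int) LENGTH(STRING_ELT(protospacers, g)) != P)
            stop("all protospacers must have the same length");
        for (int i = 0; i < P; ++i) {
            spacer[i] = baseCode(gs[i]);
            if (spacer[i] > 3) stop("protospacer contains non-ACGT base");
            spacerRC[P - 1 - i] = 3 - spacer[i];
        }
        int count = 0;
        bool sat = false;

        for (int c = 0; c < nChrom && !sat; ++c) {
            Chrom &ch = chroms[c];
            if (ch.n < L) continue;
            const int nSites = ch.n - L + 1;
            cand.clear();

            for (int strand = 0; strand < 2; ++strand) {
                const std::vector<int> &pat = strand ? spacerRC : spacer;
                const int spOff = strand ? spOffR : spOffF;
                for (int j = 0; j < nPiece; ++j) {
                    int po = j * seedW;          // piece offset in pattern
                    if (po + seedW > P) po = P - seedW;
                    uint64_t key = 0;
                    for (int i = 0; i < seedW; ++i)
                        key = (key << 2) | (uint64_t) pat[po + i];
                    SeedIndex::const_iterator it = ch.index.find(key);
                    if (it == ch.index.end()) continue;
                    const std::vector<int> &pos = it->second;
                    for (size_t pi = 0; pi < pos.size(); ++pi) {
                        int st = pos[pi] - po - spOff;
                        if (st >= 0 && st < nSites)
                            cand.push_back(std::make_pair(st, strand));
                    }
                }
            }
            std::sort(cand.begin(), cand.end());
            cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

            for (size_t ci = 0; ci < cand.size(); ++ci) {
                const int st = cand[ci].first;
                const int strand = cand[ci].second;
                if (!(strand ? ch.pamR[st] : ch.pamF[st])) continue;
                const std::vector<int> &pat = strand ? spacerRC : spacer;
                const int t0 = st + (strand ? spOffR : spOffF);
                int mm = 0;
                bool ok = true;
                for (int i = 0; i < P; ++i) {
                    uint8_t b = ch.code[t0 + i];
                    if (b > 3) { ok = false; break; }   // N in site
                    if ((int) b != pat[i] && ++mm > maxMM) {
                        ok = false; break;
                    }
                }
                if (!ok) continue;
                outGuide.push_back(g + 1);
                outChrom.push_back(c + 1);
                outStart.push_back(st);
                outStrand.push_back(strand);
                outMM.push_back(mm);
                if (++count >= hitCap) { sat = true; break; }
            }
        }
        saturated[g] = sat;
    }

    return List::create(
        _["guide"] = wrap(outGuide), _["chrom"] = wrap(outChrom),
        _["start0"] = wrap(outStart), _["strand"] = wrap(outStrand),
        _["mismatches"] = wrap(outMM), _["saturated"] = saturated);
}
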