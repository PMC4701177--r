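item_id,text,reverse_keyed
1,Seems much more fidgety in social situations than when alone,FALSE
2,Seems self-confident when interacting with others,TRUE
3,Would rather be alone than with others,FALSE
4,Shows bizarre or odd behaviors around other monkeys,FALSE
5,Is relaxed and at ease during social interactions,TRUE
6,Responds appropriately to the social cues of others,FALSE
7,Shows aggression out of proportion to the situation,FALSE
8,Reacts in expected ways to the approaches of groupmates,FALSE
9,Withdraws from ongoing social activity,FALSE
10,Moves away when others attempt to engage socially,FALSE
11,Uses facial expressions appropriate to the situation,FALSE
12,Vocalizes in ways that fit the social context,FALSE
13,Becomes agitated when social routines change,FALSE
14,Recovers quickly after tense social encounters,TRUE
15,Avoids starting social interactions with others,FALSE
16,Insists on sameness in daily social routines,FALSE
17,Is socially awkward,FALSE
18,Stays on the edge of the group rather than joining in,FALSE
19,Takes food or objects from others without typical signals,FALSE
20,Grooms others in a typical give-and-take manner,FALSE
21,Appears tense when approached by dominant individuals,FALSE
22,Plays with peers in a typical manner,FALSE
23,Initiates grooming bouts with groupmates,TRUE
24,Directs threats at inappropriate targets,FALSE
25,"Has repetitive, odd behaviors such as rocking, swaying, tumbling or spinning",FALSE
26,Maintains typical proximity to preferred partners,TRUE
27,Responds to reconciliation attempts after conflicts,FALSE
28,Holds a steady position in the group's social network,TRUE
29,Alternates attention between partners during interactions,FALSE
30,Self-directed behaviors escalate to self-injury,FALSE
31,Is too tense in social situations,FALSE
32,Approaches unfamiliar monkeys with typical caution,TRUE
33,Shares space at feeding sites without incident,FALSE
34,Shows typical interest in infants of the group,TRUE
35,Follows group movements without prompting,FALSE
36,Shows typical submission signals to dominants,FALSE
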